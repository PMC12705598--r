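# Model configurations: the 22-row switchboard of structures that were
# compared (data fusion on/off, shared vs independent fixed effects, spatial /
# shared spatio-temporal / species spatio-temporal fields, spatially varying
# year trend). Shipped as a machine-readable CSV and normalized into
# fern_config objects.

#' Construct a model configuration
#'
#' @param model Model id (e.g. "M21") or NULL for an ad-hoc config.
#' @param data_fusion Include the presence (opportunistic) likelihood.
#' @param joint_structure Species- and data-type-specific likelihoods (species
#'   intercepts, negative binomial for the overdispersed species). When FALSE
#'   all data are pooled into a single Poisson likelihood with one intercept.
#' @param shared_fixed,indep_fixed Fixed-effect estimation mode; exactly one
#'   must be TRUE.
#' @param spatial_spde Shared purely spatial field.
#' @param shared_st Shared spatio-temporal field u(s,t).
#' @param species_st Species-specific spatio-temporal fields delta_j(s,t).
#' @param svc Spatially varying year-trend coefficient omega_j(s).
#' @return Object of class \code{fern_config}.
#' @export
fern_config <- function(model = NULL, data_fusion = FALSE, joint_structure = TRUE,
                        shared_fixed = TRUE, indep_fixed = FALSE,
                        spatial_spde = FALSE, shared_st = FALSE,
                        species_st = FALSE, svc = FALSE) {
  if (shared_fixed == indep_fixed)
    stop("exactly one of shared_fixed / indep_fixed must be TRUE")
  structure(list(model = model, data_fusion = data_fusion,
                 joint_structure = joint_structure, shared_fixed = shared_fixed,
                 indep_fixed = indep_fixed, spatial_spde = spatial_spde,
                 shared_st = shared_st, species_st = species_st, svc = svc),
            class = "fern_config")
}

#' @export
print.fern_config <- function(x, ...) {
  on <- names(Filter(isTRUE, x[-1]))
  cat(sprintf("fern_config %s: %s\n", x$model %||% "(ad hoc)",
              paste(on, collapse = ", ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' The 22 evaluated model configurations
#'
#' Reads the shipped configuration table and returns one \code{fern_config}
#' per row, ids M1-M22. The baseline M1 row (no structures marked) is
#' normalized to a shared-fixed-effects GLM with no random effects, the only
#' reading under which it is a fitted model.
#'
#' @return Named list of 22 \code{fern_config} objects.
#' @export
make_configs <- function() {
  path <- system.file("extdata", "model_configs.csv", package = "fernfusion")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    sf <- r$shared_fixed == 1; inf <- r$indep_fixed == 1
    if (!sf && !inf) sf <- TRUE  # M1 baseline GLM normalization
    fern_config(model = r$model, data_fusion = r$data_fusion == 1,
                joint_structure = r$joint_structure == 1,
                shared_fixed = sf, indep_fixed = inf,
                spatial_spde = r$spatial_spde == 1, shared_st = r$shared_st == 1,
                species_st = r$species_st == 1, svc = r$svc == 1)
  })
  names(out) <- tab$model
  out
}
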