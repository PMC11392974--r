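#' Round-trip coefficient vectors through CSV
#'
#' Writes a named coefficient vector (e.g. from [fit_map()] or a
#' [true_parameters()] object) as a two-column CSV (`term`, `value`) and
#' reads it back preserving names and order.
#'
#' @param theta Named numeric vector.
#' @param path Output file.
#' @return `path` invisibly; `read_params_csv()` returns the named
#'   vector.
#' @export
write_params_csv <- function(theta, path) {
  write.csv(data.frame(term = names(theta), value = as.numeric(theta)),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path) {
  d <- read.csv(path, check.names = FALSE)
  stats::setNames(d$value, d$term)
}

#' Write posterior draws and summaries as CSV
#'
#' One column per named parameter plus `chain` and `iteration` columns;
#' optionally the summary table (posterior mean, SD, 95% interval,
#' significance flag) alongside.
#'
#' @param fit An `occu_fit` from [fit_occu()].
#' @param path Output file for the draws.
#' @param summary_path Optional output file for the summary table.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(fit, path, summary_path = NULL) {
  n_keep <- fit$n_iter - fit$n_burn
  d <- data.frame(chain = fit$chain,
                  iteration = rep(seq_len(n_keep), fit$n_chains),
                  fit$draws, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  if (!is.null(summary_path)) {
    write.csv(fit$summary, summary_path, row.names = FALSE)
  }
  invisible(path)
}

#' Serialize a model spec to and from a plain config list
#'
#' The list form is what a YAML/JSON config block holds: covariate names
#' per parameter plus species and season labels.
#'
#' @param spec An [occu_spec()].
#' @return `spec_to_config()` returns a plain named list;
#'   `spec_from_config()` rebuilds the validated [occu_spec()].
#' @export
spec_to_config <- function(spec) {
  list(phi1 = spec$phi1_terms, gamma = spec$gamma_terms,
       eps = spec$eps_terms, p = spec$p_terms,
       species = spec$species, seasons_used = spec$seasons_used)
}

#' @rdname spec_to_config
#' @param config A list as produced by `spec_to_config()` (or parsed
#'   from YAML).
#' @export
spec_from_config <- function(config) {
  occu_spec(phi1 = config$phi1, gamma = config$gamma, eps = config$eps,
            p = unlist(config$p),
            species = config$species %||% "species",
            seasons_used = config$seasons_used)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
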