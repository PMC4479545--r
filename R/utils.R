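# Internal helpers shared across modules.

#' Signal a classed codelim error
#'
#' @param msg message
#' @param class error subclass, e.g. "format" -> codelim_format_error
#' @noRd
cd_stop <- function(msg, class) {
  stop(structure(
    class = c(paste0("codelim_", class, "_error"), "codelim_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

cd_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("codelim_", class, "_warning"), "codelim_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global RNG state, so seeded internals do not
#' perturb a caller's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Derive a child seed from a master seed and a stream index
#'
#' Keeps derived seeds within the 32-bit integer range.
#' @noRd
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %%
               2147483647)
}

# column-wise standardization to mean 0, sd 1; errors on constant columns
standardize_columns <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  if (any(sdv <= 0)) {
    cd_stop(sprintf("constant column(s): %s",
                    paste(colnames(X)[sdv <= 0], collapse = ", ")),
            "degenerate")
  }
  sweep(sweep(X, 2, mu, "-"), 2, sdv, "/")
}
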