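# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so seeded package functions do
#' not perturb the user's random stream. With `seed = NULL` the current stream
#' is used (and advanced) as-is.
#'
#' @param seed integer scalar or NULL.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L) # materialize a seed to save
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps (master seed, stage label) to an integer in
#' [1, 2^31 - 2], so independent pipeline stages consume independent,
#' reproducible random streams.
#'
#' @param master integer master seed.
#' @param label character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- 0
  for (k in utf8ToInt(paste(label, collapse = "/"))) {
    h <- (h * 131 + k) %% 2147483647
  }
  as.integer((abs(master) %% 2147483647) * 48271 %% 2147483647 + h) %% 2147483646L + 1L
}

# consistent "n dropped" style messages
report_dropped <- function(what, ids) {
  if (length(ids) == 0L) return(invisible(NULL))
  shown <- paste(utils::head(ids, 10L), collapse = ", ")
  if (length(ids) > 10L) shown <- paste0(shown, ", ...")
  message(sprintf("dropped %d %s: %s", length(ids), what, shown))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
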