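# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded helpers
#' (fold assignment, simulation) do not perturb the session stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

# Coerce a column to numeric, counting cells that were non-empty text
# but failed to parse (distinct from genuinely missing).
parse_numeric <- function(x) {
  if (is.numeric(x)) return(list(value = x, bad = rep(FALSE, length(x))))
  x_chr <- trimws(as.character(x))
  val <- suppressWarnings(as.numeric(x_chr))
  bad <- is.na(val) & !is.na(x_chr) & nzchar(x_chr) &
    !(toupper(x_chr) %in% c("NA", "NAN"))
  list(value = val, bad = bad)
}
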