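#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join n across all_of desc row_number
#' @importFrom purrr map map2 map_dbl pmap imap list_rbind
#' @importFrom stats approx lm coef optimize qt sd var setNames rlnorm runif
#'   t.test median complete.cases
#' @importFrom utils head tail write.csv read.csv modifyList
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`;
# the caller's RNG stream is untouched.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# One global seed fans out to per-stage child seeds so stages can be rerun
# independently yet reproducibly. Children are drawn from the parent stream,
# all below 2^31.
derive_seeds <- function(seed, n) {
  with_local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_number <- function(x, name, positive = FALSE, non_negative = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (finite && !is.finite(x)) abort(sprintf("`%s` must be finite.", name))
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (non_negative && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

# Linear interpolation that refuses to extrapolate.
interp_at <- function(x, y, x0) {
  if (x0 < min(x) || x0 > max(x)) return(NA_real_)
  approx(x, y, xout = x0, ties = "ordered")$y
}
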