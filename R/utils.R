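# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform %||%
NULL

#' Derive a reproducible child seed from a parent seed and a label
#'
#' A single pipeline seed fans out to per-stage (and per-subject) child
#' seeds through this label-keyed mixing function, so every stage is
#' individually reproducible and independent of how many random draws
#' earlier stages consumed. The result is a valid integer seed below 2^31.
#'
#' @param seed Parent integer seed.
#' @param label Character label of the stage/object.
#' @return An integer seed.
#' @export
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  # Double arithmetic: products stay below 2^53, result below 2^31.
  as.integer((as.numeric(seed) * 2654435 + h * 97) %% 2147483587)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_number <- function(x, name, min = -Inf, max = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "adc_config_error")
  }
  if (x < min || x > max) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name,
                  format(min), format(max), format(x)),
          class = "adc_config_error")
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be an integer, got %s.", name, format(x)),
          class = "adc_config_error")
  }
  invisible(x)
}

# Population (ddof 0) or sample (ddof 1) standard deviation.
sd_ddof <- function(x, ddof = 0L) {
  n <- length(x)
  if (n <= ddof) return(NA_real_)
  m <- mean(x)
  sqrt(sum((x - m)^2) / (n - ddof))
}
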