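# broom-style tidiers for the fitted result objects

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a differential-expression result
#'
#' @param x `mirsight_de` object.
#' @param ... unused.
#' @return plain tibble of per-gene results.
#' @export
tidy.mirsight_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirsight_de")
  as_tibble(out)
}

#' One-row summary of a differential-expression result
#'
#' @param x `mirsight_de` object.
#' @param ... unused.
#' @return tibble with gene totals, thresholds and the dispersion used.
#' @export
glance.mirsight_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_significant = sum(x$significant),
    n_up = sum(x$significant & x$log2fc > 0),
    n_down = sum(x$significant & x$log2fc < 0),
    dispersion = attr(x, "dispersion"),
    alpha = attr(x, "alpha"),
    min_fold = attr(x, "min_fold")
  )
}

#' Tidy a target-shift test
#'
#' @param x `mirsight_shift` object.
#' @param ... unused.
#' @return one-row tibble with the KS statistic, p-value and direction.
#' @export
tidy.mirsight_shift <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         direction = x$direction, n_targets = x$n_targets,
         n_background = x$n_background, alternative = x$alternative)
}

#' @rdname tidy.mirsight_shift
#' @export
glance.mirsight_shift <- function(x, ...) tidy(x)
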