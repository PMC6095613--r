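#' Tidy a PID result
#'
#' @param x An `avp_pid`.
#' @param ... Unused.
#' @return Tibble with one row per decomposition term (`red`, `uni_a`,
#'   `uni_v`, `syn`) and its value in bits.
#' @method tidy avp_pid
#' @export
tidy.avp_pid <- function(x, ...) {
  tibble(
    term = pid_terms,
    estimate = unlist(x[pid_terms], use.names = FALSE),
    mc_se = x$mc_se
  )
}

#' @rdname tidy.avp_pid
#' @return `glance()`: one-row tibble with the three MIs, the interaction
#'   information, and the Monte-Carlo settings.
#' @method glance avp_pid
#' @export
glance.avp_pid <- function(x, ...) {
  tibble(
    mi_a = x$mi_a, mi_v = x$mi_v, mi_av = x$mi_av,
    interaction = x$mi_av - x$mi_a - x$mi_v,
    mc_samples = x$mc_samples, mc_se = x$mc_se, rng_seed = x$rng_seed
  )
}

#' @method tidy avp_contrast
#' @export
tidy.avp_contrast <- function(x, ...) as_tibble(as.data.frame(x))

#' @method glance avp_contrast
#' @export
glance.avp_contrast <- function(x, ...) {
  tibble(
    n_cells = nrow(x),
    n_significant = sum(x$significant),
    n_perm = attr(x, "n_perm") %||% NA_integer_
  )
}

#' Plot an MI profile
#'
#' Spectral profiles are drawn over frequency, delayed-MI profiles over lag.
#'
#' @param object An `avp_mi_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot avp_mi_profile
#' @export
autoplot.avp_mi_profile <- function(object, ...) {
  axis <- attr(object, "axis")
  xlab <- if (identical(axis, "lag_ms")) "Lag (ms)" else "Frequency (Hz)"
  ggplot2::ggplot(
    as_tibble(as.data.frame(object)),
    ggplot2::aes(x = .data[[axis]], y = .data$mi)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xlab, y = "MI (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a PID decomposition
#'
#' @param object An `avp_pid`.
#' @param ... Unused.
#' @return A ggplot bar chart of the four terms.
#' @method autoplot avp_pid
#' @export
autoplot.avp_pid <- function(object, ...) {
  d <- tidy(object)
  d$term <- factor(d$term, levels = pid_terms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$estimate - .data$mc_se,
        ymax = .data$estimate + .data$mc_se
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "Information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot cohort information maps
#'
#' Surrogate-normalised values per node and term, one point per subject.
#'
#' @param object An `avp_info_maps` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot avp_info_maps
#' @export
autoplot.avp_info_maps <- function(object, ...) {
  d <- surrogate_normalise(object)
  d <- as_tibble(as.data.frame(d))
  d$term <- factor(d$term, levels = pid_terms)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$term, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red", size = 2) +
    ggplot2::facet_wrap(~node) +
    ggplot2::labs(x = NULL, y = "Normalised information (bits)") +
    ggplot2::theme_minimal()
}

#' Plot a local probability-weighted information map
#'
#' Quadrant maps of per-cell `p * i` contributions, faceted by the target's
#' median split, for the joint MI and the Iccs redundancy integrand.
#'
#' @param object An `avp_local_map`.
#' @param quantity `"pi_mi"` or `"pi_red"`.
#' @param ... Unused.
#' @return A ggplot tile map.
#' @method autoplot avp_local_map
#' @export
autoplot.avp_local_map <- function(object, quantity = c("pi_mi", "pi_red"), ...) {
  quantity <- match.arg(quantity)
  d <- as_tibble(as.data.frame(object))
  d$m_bin <- paste("M", d$m_bin)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$a_bin, y = .data$v_bin, fill = .data[[quantity]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~m_bin) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::labs(x = "Auditory (vs median)", y = "Visual (vs median)", fill = "p·i (bits)") +
    ggplot2::theme_minimal()
}
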