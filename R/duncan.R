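#' Duncan's multiple range test
#'
#' Protected step-down multiple comparison of group means after a one-way
#' ANOVA.  Means are sorted and the range of every span `p` is compared
#' against the least significant range
#' `LSR_p = q(1 - alpha_p, p, df) * sqrt(MSE / n_h)`, where `q` is the
#' studentized-range quantile, `alpha_p = 1 - (1 - alpha)^(p - 1)` is
#' Duncan's protection level, and `n_h` the harmonic mean group size
#' (the usual approximation for unequal replication).  A non-significant
#' range suppresses all of its sub-ranges (the classical step-down rule),
#' which makes the family error under a complete null exactly the
#' protection level for the full span.  Groups are then lettered so that
#' groups sharing a letter are not significantly different.
#'
#' Homoscedasticity is assumed (the pooled ANOVA mean square is used
#' throughout).  With two groups the decision coincides with Fisher's
#' LSD, since the protection level collapses to `alpha` and
#' `q(1 - alpha, 2, df) = sqrt(2) * t(1 - alpha/2, df)`.
#'
#' @param data A data frame with one observation per row, or a named list
#'   of replicate vectors (each group needs at least two replicates).
#' @param value,group Column names (strings) in `data` holding the
#'   response and the group label; ignored for list input.
#' @param alpha Comparison-wise significance level (default 0.05, i.e.
#'   the 95% confidence level).
#' @return An object of class `duncan_mrt`: a list with `groups` (tibble
#'   of `group`, `n`, `mean`, `letters`, sorted by decreasing mean),
#'   `comparisons` (tibble of pairwise range tests actually performed),
#'   `alpha`, `df_error` and `mse`.
#' @examples
#' set.seed(1)
#' d <- data.frame(y = c(rnorm(5, 0), rnorm(5, 100)),
#'                 g = rep(c("a", "b"), each = 5))
#' duncan_mrt(d, "y", "g")
#' @export
duncan_mrt <- function(data, value = "value", group = "group",
                       alpha = 0.05) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) names(data) <- paste0("g", seq_along(data))
    data <- purrr::imap_dfr(data, ~ tibble::tibble(value = .x, group = .y))
    value <- "value"
    group <- "group"
  }
  stopifnot(alpha > 0, alpha < 1)
  df <- tibble::tibble(value = as.numeric(data[[value]]),
                       group = as.character(data[[group]]))
  df <- df[is.finite(df$value), ]
  sizes <- table(df$group)
  if (length(sizes) < 2L) stop("need at least two groups", call. = FALSE)
  if (any(sizes < 2L)) {
    stop("group(s) with fewer than 2 replicates: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  fit <- stats::aov(value ~ group, data = df)
  # zero residual variance (identical replicates) is legitimate here;
  # only the pooled MSE and df are consumed, not the F test
  an <- suppressWarnings(stats::anova(fit))
  mse <- an["Residuals", "Mean Sq"]
  df_err <- an["Residuals", "Df"]
  stats_tbl <- df |>
    dplyr::group_by(group) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(value), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(mean), group)
  k <- nrow(stats_tbl)
  n_h <- k / sum(1 / stats_tbl$n)               # harmonic mean group size
  se <- sqrt(mse / n_h)
  lsr <- function(p) {
    alpha_p <- 1 - (1 - alpha)^(p - 1)
    stats::qtukey(1 - alpha_p, p, df_err) * se
  }

  # step-down sweep over spans, largest first; a non-significant range
  # freezes all of its sub-ranges as non-significant without testing
  decided <- matrix(NA_character_, k, k)
  comps <- list()
  if (k >= 2) {
    for (p in seq(k, 2)) {
      for (i in seq_len(k - p + 1L)) {
        j <- i + p - 1L
        if (!is.na(decided[i, j])) next
        diff <- stats_tbl$mean[i] - stats_tbl$mean[j]
        crit <- lsr(p)
        sig <- diff > crit + 1e-12
        comps[[length(comps) + 1L]] <- tibble::tibble(
          group_hi = stats_tbl$group[i], group_lo = stats_tbl$group[j],
          diff = diff, span = p, lsr = crit, significant = sig
        )
        if (sig) {
          decided[i, j] <- "sig"
        } else {
          for (a in i:(j - 1L)) for (b in (a + 1L):j) {
            if (is.na(decided[a, b])) decided[a, b] <- "nonsig"
          }
        }
      }
    }
  }

  # letter display from maximal non-significant stretches of sorted means
  intervals <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && identical(decided[i, j + 1L], "nonsig")) j <- j + 1L
    intervals[[i]] <- c(i, j)
  }
  keep <- rep(TRUE, length(intervals))
  for (a in seq_along(intervals)) {
    for (b in seq_along(intervals)) {
      if (a != b && intervals[[a]][1] >= intervals[[b]][1] &&
          intervals[[a]][2] <= intervals[[b]][2] &&
          !identical(intervals[[a]], intervals[[b]])) {
        keep[a] <- FALSE
      }
    }
  }
  intervals <- unique(intervals[keep])
  letter_of <- rep("", k)
  for (s in seq_along(intervals)) {
    rng <- intervals[[s]][1]:intervals[[s]][2]
    letter_of[rng] <- paste0(letter_of[rng], letters[s])
  }
  stats_tbl$letters <- letter_of

  structure(
    list(groups = stats_tbl,
         comparisons = if (length(comps)) dplyr::bind_rows(comps)
                       else tibble::tibble(),
         alpha = alpha, df_error = df_err, mse = mse),
    class = "duncan_mrt"
  )
}

#' @export
print.duncan_mrt <- function(x, ...) {
  cat(sprintf(
    "Duncan's multiple range test (alpha = %g, df = %d, MSE = %.4g)\n",
    x$alpha, x$df_error, x$mse))
  cat("groups sharing a letter are not significantly different\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  invisible(x)
}

#' Tidy the group table of a Duncan comparison
#'
#' @param x A `duncan_mrt`.
#' @param ... Unused.
#' @method tidy duncan_mrt
#' @export
tidy.duncan_mrt <- function(x, ...) x$groups

#' One-row summary of a Duncan comparison
#'
#' @param x A `duncan_mrt`.
#' @param ... Unused.
#' @method glance duncan_mrt
#' @export
glance.duncan_mrt <- function(x, ...) {
  tibble::tibble(k = nrow(x$groups), alpha = x$alpha,
                 df_error = x$df_error, mse = x$mse,
                 n_distinct_letters =
                   length(unique(unlist(strsplit(x$groups$letters, "")))))
}
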