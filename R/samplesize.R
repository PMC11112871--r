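# Minimal sample-size determination by quantile resampling.
#
# For a trait measured on all available fruit of a cultivar, subsets of
# size n are drawn repeatedly and the spread of the subset means is turned
# into a relative margin of error: half the 2.5%-97.5% quantile range of
# the subset means, divided by the full-sample mean. Curves of this margin
# over n answer how many fruit are needed for a given description accuracy.

#' Relative margin of error of a trait mean at sample size n
#'
#' Draws `reps` random subsets of size `n` (without replacement by
#' default), takes each subset's mean, and computes
#' `rel_moe = (q97.5 - q2.5) / (2 * full_mean)` where the quantiles are
#' over the subset means (type-7, linear interpolation) and `full_mean` is
#' the mean of all values.
#'
#' @param values numeric vector of trait values for one cultivar (>= 2).
#' @param n subset size, 1 <= n <= length(values).
#' @param reps number of resamples (>= 2).
#' @param seed RNG seed; recorded in the result.
#' @param replace set TRUE for a with-replacement bootstrap instead of
#'   subset sampling.
#' @param probs quantile pair defining the interval.
#' @param cultivar,trait optional labels carried into the result.
#' @return One-row data frame of class `moe_result` with columns
#'   `cultivar`, `trait`, `n`, `reps`, `q_low`, `q_high`, `full_mean`,
#'   `rel_moe`, `seed`.
#' @export
margin_of_error <- function(values, n, reps = 200L, seed = NULL,
                            replace = FALSE, probs = c(0.025, 0.975),
                            cultivar = NA_character_,
                            trait = NA_character_) {
  values <- as.numeric(values)
  N <- length(values)
  if (N < 2L) stop("need at least 2 values", call. = FALSE)
  if (n < 1L || (!replace && n > N))
    stop("n must be between 1 and the number of values", call. = FALSE)
  if (reps < 2L) stop("reps must be at least 2", call. = FALSE)
  means <- with_seed(seed, vapply(seq_len(reps), function(i) {
    mean(values[sample.int(N, n, replace = replace)])
  }, numeric(1)))
  q <- stats::quantile(means, probs = probs, names = FALSE, type = 7)
  full_mean <- mean(values)
  structure(data.frame(cultivar = cultivar, trait = trait, n = as.integer(n),
                       reps = as.integer(reps), q_low = q[1L],
                       q_high = q[2L], full_mean = full_mean,
                       rel_moe = (q[2L] - q[1L]) / (2 * full_mean),
                       seed = if (is.null(seed)) NA_integer_
                              else as.integer(seed)),
            class = c("moe_result", "data.frame"))
}

#' Margin-of-error curves over a grid of sample sizes
#'
#' Computes [margin_of_error()] for every cultivar, trait and sample size
#' in a grid, plus the cross-cultivar mean relative margin per trait and
#' n, and a recommended minimal n for a target margin. Cultivars with
#' fewer fruit than the largest grid value get a truncated grid (with a
#' warning).
#'
#' @param records data frame with a `cultivar` column and trait columns.
#' @param traits trait column names.
#' @param n_grid sample sizes to evaluate.
#' @param reps resamples per (cultivar, trait, n).
#' @param seed base seed; each (cultivar, trait, n) cell uses a distinct
#'   seed derived from it, so results are reproducible and independent of
#'   evaluation order.
#' @param target_rel_moe target used for the recommendation.
#' @inheritParams margin_of_error
#' @return List of class `moe_curve` with `results` (long data frame),
#'   `by_n` (trait x n cross-cultivar mean rel_moe), `recommended_n`
#'   (named per trait: smallest grid n whose cross-cultivar mean margin is
#'   at or below the target, NA if never) and `target_rel_moe`.
#' @export
moe_curve <- function(records,
                      traits = c("height_mean_cm", "width_mean_cm",
                                 "weight_g"),
                      n_grid = 5:50, reps = 200L, seed = 1L,
                      replace = FALSE, target_rel_moe = 0.05) {
  stopifnot("cultivar" %in% names(records), nrow(records) > 0L)
  traits <- intersect(traits, names(records))
  if (!length(traits)) stop("no requested trait columns present",
                            call. = FALSE)
  cultivars <- sort(unique(records$cultivar))
  out <- list(); cell <- 0L
  for (cv in cultivars) {
    for (tr in traits) {
      v <- records[[tr]][records$cultivar == cv]
      v <- v[is.finite(v)]
      grid <- n_grid[n_grid <= length(v)]
      if (length(grid) < length(n_grid))
        warning("cultivar ", cv, " has only ", length(v), " values for ",
                tr, "; grid truncated")
      for (n in grid) {
        cell <- cell + 1L
        out[[cell]] <- margin_of_error(
          v, n, reps = reps,
          seed = (seed + 7919L * cell) %% .Machine$integer.max,
          replace = replace, cultivar = cv, trait = tr)
      }
    }
  }
  if (!length(out))
    stop("no cultivar has enough records for any sample size in n_grid",
         call. = FALSE)
  results <- do.call(rbind, out)
  by_n <- stats::aggregate(rel_moe ~ trait + n, data = results, FUN = mean)
  rec <- vapply(traits, function(tr) {
    sub <- by_n[by_n$trait == tr, ]
    sub <- sub[order(sub$n), ]
    hit <- which(sub$rel_moe <= target_rel_moe)
    if (length(hit)) sub$n[hit[1L]] else NA_integer_
  }, integer(1))
  structure(list(results = results, by_n = by_n, recommended_n = rec,
                 target_rel_moe = target_rel_moe, seed = seed),
            class = "moe_curve")
}

#' Export margin-of-error results as text
#'
#' @param curve a [moe_curve()] result (or a `moe_result` data frame).
#' @param path output path (tab-delimited).
#' @return `path`, invisibly.
#' @export
export_moe <- function(curve, path) {
  df <- if (inherits(curve, "moe_curve")) curve$results else curve
  utils::write.table(format(df, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Plot margin-of-error curves
#'
#' One panel per trait: per-cultivar curves (thin) and the cross-cultivar
#' mean (thick) of the relative margin of error against sample size.
#'
#' @param curve a [moe_curve()] result.
#' @return A ggplot object.
#' @export
plot_moe_curve <- function(curve) {
  stopifnot(inherits(curve, "moe_curve"))
  res <- curve$results
  ggplot2::ggplot(res, ggplot2::aes(x = n, y = rel_moe)) +
    ggplot2::geom_line(ggplot2::aes(group = cultivar),
                       linewidth = 0.3, alpha = 0.5) +
    ggplot2::geom_line(data = curve$by_n, linewidth = 1.1,
                       color = "firebrick") +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::scale_y_continuous(labels = function(x)
      sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = "sample size n",
                  y = "relative margin of error") +
    ggplot2::theme_minimal()
}
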