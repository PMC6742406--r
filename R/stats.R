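# Two-factor repeated-measures ANOVA on band power (MW condition x
# frequency band), partial eta squared, Holm correction, post-hoc paired t.

#' Aggregate band powers into unit x condition x band cell means
#'
#' Builds the complete crossed design the repeated-measures ANOVA needs:
#' one mean (log-)power value per unit, MW condition and frequency band.
#' With `unit_kind = "channel"` the units are the channels of a single
#' subject's band-power table (one per-participant model). With
#' `unit_kind = "participant"` the units are subjects: `powers` is then a
#' list of per-subject tables and `channel` selects the channel under test
#' (one per-channel model). Units missing a cell (e.g. a subject without
#' epochs of one class) are dropped with a warning.
#'
#' @param powers A `band_power_table`, or a list of them for
#'   `unit_kind = "participant"`.
#' @param unit_kind `"channel"` or `"participant"`.
#' @param channel Channel label (required for `unit_kind = "participant"`).
#' @param use_log Analyze log power (default TRUE; skipped when the table
#'   already holds log power).
#' @return A list of class `cell_means`: `values` (unit x 2 x band array
#'   with condition dimnames `MW`, `NOT_MW`), `unit_kind`, `n_units`.
#' @export
aggregate_cell_means <- function(powers, unit_kind = c("channel", "participant"),
                                 channel = NULL, use_log = TRUE) {
  unit_kind <- match.arg(unit_kind)
  prep <- function(tbl) {
    v <- tbl$values
    if (use_log && !isTRUE(tbl$log_power)) v <- log(v)
    v
  }
  if (unit_kind == "channel") {
    stopifnot(inherits(powers, "band_power_table"), !is.null(powers$labels))
    v <- prep(powers)
    units <- powers$channel_labels
    n_bands <- dim(v)[3]
    vals <- array(NA_real_, c(length(units), 2, n_bands),
                  dimnames = list(units, c("MW", "NOT_MW"),
                                  dimnames(v)[[3]]))
    for (cond in c("MW", "NOT_MW")) {
      idx <- which(powers$labels == cond)
      if (length(idx) > 0) {
        vals[, cond, ] <- apply(v[idx, , , drop = FALSE], c(2, 3), mean)
      }
    }
  } else {
    stopifnot(is.list(powers), !is.null(channel))
    tabs <- powers
    units <- vapply(tabs, `[[`, "", "subject_id")
    n_bands <- dim(tabs[[1]]$values)[3]
    vals <- array(NA_real_, c(length(units), 2, n_bands),
                  dimnames = list(units, c("MW", "NOT_MW"),
                                  dimnames(tabs[[1]]$values)[[3]]))
    for (s in seq_along(tabs)) {
      ch <- match(channel, tabs[[s]]$channel_labels)
      if (is.na(ch)) next  # channel removed for this subject
      v <- prep(tabs[[s]])
      for (cond in c("MW", "NOT_MW")) {
        idx <- which(tabs[[s]]$labels == cond)
        if (length(idx) > 0) {
          vals[s, cond, ] <- apply(v[idx, ch, , drop = FALSE], 3L, mean)
        }
      }
    }
  }
  complete <- apply(vals, 1L, function(m) all(is.finite(m)))
  if (!all(complete)) {
    warning(sprintf("dropping %d unit(s) with incomplete cells", sum(!complete)))
    vals <- vals[complete, , , drop = FALSE]
  }
  if (dim(vals)[1] < 2) stop("fewer than 2 complete units")
  structure(list(values = vals, unit_kind = unit_kind, n_units = dim(vals)[1]),
            class = "cell_means")
}

#' Two-factor repeated-measures ANOVA (2 conditions x 4 bands)
#'
#' Univariate within-unit decomposition with a separate error term per
#' effect: the condition effect is tested against its condition-by-unit
#' interaction (df 1, n-1), the condition-by-band interaction against the
#' three-way interaction (df 3, 3(n-1)). No sphericity correction is
#' applied by default (`gg_correction = TRUE` enables
#' Greenhouse-Geisser on the interaction test).
#'
#' @param cells A [aggregate_cell_means()] result.
#' @param gg_correction Apply Greenhouse-Geisser correction (default FALSE).
#' @return An object of class `mw_anova`: a data.frame `table` with rows
#'   `MW` and `MW x Freq` (columns `F`, `df1`, `df2`, `p`, `eta_p2`,
#'   `ss_effect`, `ss_error`) and the full `ss` decomposition.
#' @export
rm_anova_2x4 <- function(cells, gg_correction = FALSE) {
  stopifnot(inherits(cells, "cell_means"))
  v <- cells$values
  n <- dim(v)[1]
  if (n < 3) stop("need at least 3 units")
  a <- dim(v)[2]
  b <- dim(v)[3]
  df <- data.frame(
    y = as.vector(v),
    unit = factor(rep(seq_len(n), a * b)),
    mw = factor(rep(rep(c("MW", "NOT_MW"), each = n), b)),
    band = factor(rep(dimnames(v)[[3]], each = n * a))
  )
  fit <- stats::aov(y ~ mw * band + Error(unit / (mw * band)), data = df)
  sm <- summary(fit)
  grab <- function(stratum, term) {
    tb <- sm[[stratum]][[1]]
    rn <- trimws(rownames(tb))
    i <- match(term, rn)
    j <- match("Residuals", rn)
    list(F = tb[i, "F value"], df1 = tb[i, "Df"], df2 = tb[j, "Df"],
         p = tb[i, "Pr(>F)"], ss_effect = tb[i, "Sum Sq"],
         ss_error = tb[j, "Sum Sq"])
  }
  mw <- grab("Error: unit:mw", "mw")
  ib <- grab("Error: unit:mw:band", "mw:band")
  if (gg_correction) {
    # GG epsilon from the covariance of the unit x (mw x band) interaction
    # contrasts of the 4 band-difference scores
    dmat <- v[, 1, ] - v[, 2, ]            # n x b difference scores
    S <- stats::cov(dmat)
    k <- nrow(S)
    ctr <- diag(k) - 1 / k
    Sc <- ctr %*% S %*% ctr
    eps <- sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
    ib$p <- stats::pf(ib$F, ib$df1 * eps, ib$df2 * eps, lower.tail = FALSE)
  }
  row <- function(g) {
    data.frame(F = g$F, df1 = g$df1, df2 = g$df2, p = g$p,
               eta_p2 = partial_eta_squared(g$ss_effect, g$ss_error),
               ss_effect = g$ss_effect, ss_error = g$ss_error)
  }
  tab <- rbind(MW = row(mw), `MW x Freq` = row(ib))
  ss_all <- lapply(sm, function(s) {
    tb <- s[[1]]
    stats::setNames(tb[, "Sum Sq"], trimws(rownames(tb)))
  })
  structure(list(table = tab, ss = ss_all, n_units = n,
                 unit_kind = cells$unit_kind),
            class = "mw_anova")
}

#' @export
print.mw_anova <- function(x, ...) {
  cat(sprintf("<mw_anova> repeated measures over %d %ss\n",
              x$n_units, x$unit_kind))
  tb <- x$table
  for (i in seq_len(nrow(tb))) {
    cat(sprintf("  %-9s F(%d,%d) = %.2f, p = %.4g, eta_p2 = %.2f\n",
                rownames(tb)[i], tb$df1[i], tb$df2[i], tb$F[i], tb$p[i],
                tb$eta_p2[i]))
  }
  invisible(x)
}

#' Partial eta squared
#'
#' Effect size `ss_effect / (ss_effect + ss_error)`. The equivalent
#' computation from a reported F statistic and its degrees of freedom is
#' [partial_eta_squared_f()].
#'
#' @param ss_effect,ss_error Sums of squares (non-negative, not both zero).
#' @return Value in `[0, 1]`.
#' @export
partial_eta_squared <- function(ss_effect, ss_error) {
  stopifnot(ss_effect >= 0, ss_error >= 0)
  if (ss_effect + ss_error == 0) stop("both sums of squares are zero")
  ss_effect / (ss_effect + ss_error)
}

#' @rdname partial_eta_squared
#' @param f F statistic.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @export
partial_eta_squared_f <- function(f, df1, df2) {
  stopifnot(f >= 0, df1 > 0, df2 > 0)
  f * df1 / (f * df1 + df2)
}

#' Holm-Bonferroni step-down correction
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (elementwise >= input, capped at 1),
#'   in the input order.
#' @export
holm_bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "holm")
}

#' Post-hoc paired t-tests per band
#'
#' Paired t-test of MW versus not-MW cell means across units, one test per
#' frequency band. Uncorrected p-values are reported. Zero-variance
#' difference vectors are handled explicitly: all-zero differences give
#' t = 0, p = 1; constant non-zero differences give an infinite t with
#' p = 0.
#'
#' @param cells A [aggregate_cell_means()] result (>= 2 units).
#' @return Data.frame with columns `band`, `t`, `df`, `p`,
#'   `mean_difference` (MW minus not-MW).
#' @export
posthoc_paired_t <- function(cells) {
  stopifnot(inherits(cells, "cell_means"))
  v <- cells$values
  if (dim(v)[1] < 2) stop("need at least 2 paired units")
  bands <- dimnames(v)[[3]]
  out <- lapply(seq_along(bands), function(b) {
    d <- v[, "MW", b] - v[, "NOT_MW", b]
    if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
      data.frame(band = bands[b], t = t, df = length(d) - 1, p = p,
                 mean_difference = mean(d))
    } else {
      tt <- stats::t.test(v[, "MW", b], v[, "NOT_MW", b], paired = TRUE)
      data.frame(band = bands[b], t = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 mean_difference = mean(d))
    }
  })
  do.call(rbind, out)
}
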