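#' One-dimensional kernel density estimate
#'
#' Gaussian-kernel density of a rotation sample, bandwidth by Silverman's
#' rule of thumb unless overridden. Thin wrapper over [stats::density()]
#' that enforces the contracts the analysis relies on (error on
#' zero-variance input, density integrating to 1 over the grid).
#'
#' @param x numeric sample (angles in degrees), at least 2 finite values.
#' @param bw bandwidth: `"silverman"` or a positive number.
#' @param n grid size.
#' @param from,to optional grid limits.
#' @return A data.frame with columns `x` (grid) and `density`.
#' @export
kde_1d <- function(x, bw = "silverman", n = 512, from = NULL, to = NULL) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite samples", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("zero-variance input: supply a fixed numeric bandwidth", call. = FALSE)
  bw_val <- if (identical(bw, "silverman")) stats::bw.nrd0(x) else bw
  args <- list(x = x, bw = bw_val, kernel = "gaussian", n = n)
  if (!is.null(from)) args$from <- from
  if (!is.null(to)) args$to <- to
  d <- do.call(stats::density, args)
  data.frame(x = d$x, density = d$y)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Compares the empirical distributions of two rotation samples;
#' `D = sup |ECDF_a - ECDF_b|`, with the asymptotic p-value (sample sizes in
#' this analysis are thousands of rotation samples, where the asymptotic
#' null is accurate).
#'
#' @param a,b numeric samples, non-empty.
#' @return A `ks_result`: list with `statistic` (D), `p_value`, `n_a`, `n_b`.
#' @export
ks_two_sample <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  structure(list(statistic = unname(kt$statistic),
                 p_value = unname(kt$p.value),
                 n_a = length(a), n_b = length(b)),
            class = "ks_result")
}

#' Box-Cox skew correction, applied only when normality is rejected
#'
#' Gates on a Shapiro-Wilk normality test at `alpha`: if normality is not
#' rejected the values are returned unchanged. Otherwise the values are
#' shifted to positivity if needed (by `-min + eps`), the Box-Cox exponent
#' `lambda` is estimated by profile maximum likelihood, and the transformed
#' values `(x^lambda - 1)/lambda` (or `log(x)` at `lambda = 0`) are
#' returned with a record of the transform. Constant input is returned
#' unchanged with a warning record.
#'
#' @param x numeric values (finite).
#' @param alpha significance level of the normality gate.
#' @return A list with `values` and `record` (`NULL` when untransformed;
#'   otherwise `lambda`, `shift`, `skew_before`, `skew_after`).
#' @export
boxcox_if_skewed <- function(x, alpha = 0.05) {
  if (!all(is.finite(x))) stop("values must be finite", call. = FALSE)
  if (stats::sd(x) == 0) {
    warning("constant input: no transform applied")
    return(list(values = x,
                record = list(lambda = NA, shift = 0,
                              skew_before = 0, skew_after = 0,
                              note = "constant input")))
  }
  xs <- if (length(x) > 5000) x[round(seq(1, length(x), length.out = 5000))] else x
  if (stats::shapiro.test(xs)$p.value >= alpha) {
    return(list(values = x, record = NULL))
  }
  shift <- if (min(x) <= 0) -min(x) + 1e-6 * max(diff(range(x)), 1) else 0
  xp <- x + shift
  bc <- MASS::boxcox(xp ~ 1, lambda = seq(-3, 3, 0.01), plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  y <- if (abs(lambda) < 1e-8) log(xp) else (xp^lambda - 1) / lambda
  list(values = y,
       record = list(lambda = lambda, shift = shift,
                     skew_before = skewness(x), skew_after = skewness(y)))
}

#' Condition-by-group ANOVA on session-level outcomes
#'
#' Two-way ANOVA of one outcome per session on vision condition (optimal /
#' degraded, within-subject) and degradation group (lower / higher,
#' between-subject). Two modes are offered:
#' \describe{
#'   \item{`paper_df`}{fixed-effects two-way ANOVA on the session-level
#'     values, error df = N_sessions - 4 — at 21 participants x 2
#'     conditions this yields df (1, 38) for every effect, the structure
#'     printed in the replication target's tables (default for replication
#'     output).}
#'   \item{`mixed`}{the statistically conventional mixed ANOVA: the group
#'     effect is tested against the between-participant stratum and the
#'     condition and interaction effects against the within-participant
#'     stratum.}
#' }
#' Effect sizes are `eta^2 = SS_effect / SS_total` in both modes.
#'
#' @param data data.frame with columns `value`, `condition`, `group`,
#'   `participant` (one row per session).
#' @param mode `"paper_df"` or `"mixed"`.
#' @return An `anova_result` data.frame: one row per effect with `F`,
#'   `df_num`, `df_den`, `p`, `eta_sq`, plus attribute `mode`.
#' @export
anova_condition_group <- function(data, mode = c("paper_df", "mixed")) {
  mode <- match.arg(mode)
  req <- c("value", "condition", "group", "participant")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  data$condition <- factor(data$condition)
  data$group <- factor(data$group)
  data$participant <- factor(data$participant)
  cells <- table(data$condition, data$group)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("empty condition x group cells: ",
         paste(sprintf("(%s, %s)", rownames(cells)[empty[, 1]],
                       colnames(cells)[empty[, 2]]), collapse = ", "),
         call. = FALSE)
  }
  ss_total <- sum((data$value - mean(data$value))^2)
  effects <- c("condition", "group", "condition:group")
  if (mode == "paper_df") {
    aovtab <- stats::anova(stats::lm(value ~ condition * group, data = data))
    rows <- lapply(effects, function(e) {
      data.frame(effect = e, F = aovtab[e, "F value"],
                 df_num = aovtab[e, "Df"],
                 df_den = aovtab["Residuals", "Df"],
                 p = aovtab[e, "Pr(>F)"],
                 eta_sq = aovtab[e, "Sum Sq"] / ss_total)
    })
    out <- do.call(rbind, rows)
    attr(out, "ss") <- c(aovtab[, "Sum Sq"], total = ss_total)
  } else {
    fit <- stats::aov(value ~ condition * group + Error(participant),
                      data = data)
    sm <- summary(fit)
    btw <- sm[["Error: participant"]][[1]]
    wth <- sm[["Error: Within"]][[1]]
    pick <- function(tab, nm) {
      rn <- trimws(rownames(tab))
      i <- match(nm, rn)
      r <- match("Residuals", rn)
      data.frame(effect = nm, F = tab[i, "F value"], df_num = tab[i, "Df"],
                 df_den = tab[r, "Df"], p = tab[i, "Pr(>F)"],
                 eta_sq = tab[i, "Sum Sq"] / ss_total)
    }
    out <- rbind(pick(wth, "condition"), pick(btw, "group"),
                 pick(wth, "condition:group"))
  }
  rownames(out) <- NULL
  attr(out, "mode") <- mode
  class(out) <- c("anova_result", "data.frame")
  out
}

#' Tukey HSD pairwise comparisons across condition x group cells
#'
#' Studentized-range post-hoc comparisons between the four condition x
#' group cells (Tukey-Kramer for unequal cell sizes). Cells with fewer than
#' 2 observations are excluded with a warning.
#'
#' @param data data.frame with columns `value`, `condition`, `group`.
#' @return A data.frame with one row per cell pair: `diff`, `lwr`, `upr`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data) {
  stopifnot(all(c("value", "condition", "group") %in% names(data)))
  cell <- interaction(data$condition, data$group, drop = TRUE, sep = ":")
  sizes <- table(cell)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding cells with n < 2: ", paste(small, collapse = ", "))
    keep <- !(cell %in% small)
    data <- data[keep, , drop = FALSE]
    cell <- droplevels(cell[keep])
  }
  if (nlevels(cell) < 2) stop("need at least 2 cells", call. = FALSE)
  fit <- stats::aov(data$value ~ cell)
  tk <- stats::TukeyHSD(fit)$cell
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"])
  rownames(out) <- NULL
  out
}
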