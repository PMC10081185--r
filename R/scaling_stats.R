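# R^2 without summary.lm (which warns on numerically perfect fits)
r_squared <- function(fit) {
  y <- fit$residuals + fit$fitted.values
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  max(0, min(1, 1 - sum(fit$residuals^2) / ss_tot))
}

#' Branching ratio from per-order segment counts
#'
#' Ordinary least squares of `ln N` on Strahler order `O` over orders with
#' at least one segment. The branching ratio is the per-order count decay
#' factor `gamma = exp(-slope)`; `N0 = exp(intercept)` is the
#' intercept-scale count.
#'
#' @param counts data.frame with `order` and `n` (see [order_counts()]).
#' @return A `branching_ratio_fit` list: `gamma`, `N0`, `slope`,
#'   `intercept`, `r2`, `orders_used`.
#' @export
fit_branching_ratio <- function(counts) {
  use <- counts$n >= 1
  if (sum(use) < 2) stop("need at least 2 orders with N >= 1")
  o <- counts$order[use]; n <- counts$n[use]
  fit <- lm(log(n) ~ o)
  structure(list(gamma = exp(-unname(coef(fit)[2])),
                 N0 = exp(unname(coef(fit)[1])),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r_squared(fit),
                 orders_used = o),
            class = "branching_ratio_fit")
}

#' @export
print.branching_ratio_fit <- function(x, ...) {
  cat(sprintf("branching ratio gamma = %.4f (N0 = %.1f, R^2 = %.3f, %d orders)\n",
              x$gamma, x$N0, x$r2, length(x$orders_used)))
  invisible(x)
}

#' Extract bifurcation records (parent and child radii at junctions)
#'
#' One record per junction node (a node with two or more children away
#' from the root); the parent segment is the unique segment toward the
#' root. Radii are mean segment radii.
#'
#' @param g a [spatial_graph].
#' @param metrics [segment_metrics()] table.
#' @param ordering optional `ordering_result`; adds each record's parent
#'   Strahler order.
#' @param root root node id; defaults to the root stored in `ordering`, or
#'   [find_root()] otherwise.
#' @return data.frame with `node_id`, `parent_segment`, `parent_radius`,
#'   `parent_order`, `n_children`, and `child_radii` (list column).
#' @export
extract_bifurcations <- function(g, metrics, ordering = NULL, root = NULL) {
  if (is.null(root))
    root <- if (!is.null(ordering)) attr(ordering, "root") else find_root(g)
  rt <- root_tree(g, root)
  rad <- metrics$radius[match(g$segments$id, metrics$segment_id)]
  ord <- if (!is.null(ordering))
    ordering$strahler[match(g$segments$id, ordering$segment_id)] else
      rep(NA_integer_, nrow(g$segments))
  recs <- list()
  for (k in seq_len(nrow(g$segments))) {
    if (!rt$in_component[k]) next
    ch <- rt$children[[k]]
    if (length(ch) < 2) next
    recs[[length(recs) + 1L]] <- data.frame(
      node_id = g$nodes$id[rt$far_node_idx[k]],
      parent_segment = g$segments$id[k],
      parent_radius = rad[k],
      parent_order = ord[k],
      n_children = length(ch))
    recs[[length(recs)]]$child_radii <- list(rad[ch])
  }
  if (!length(recs))
    return(data.frame(node_id = integer(0), parent_segment = integer(0),
                      parent_radius = numeric(0), parent_order = integer(0),
                      n_children = integer(0),
                      child_radii = I(list())))
  do.call(rbind, recs)
}

#' Robust FDR-based outlier removal for paired observations
#'
#' An approximation of robust-regression-and-outlier-removal at a maximum
#' false discovery rate `Q`: a least-absolute-deviations line is fitted by
#' iteratively reweighted least squares, the residual scale is taken as
#' the 68.27th percentile of absolute residuals, per-point t-like
#' statistics are converted to p-values (t distribution, n - 2 df) and a
#' Benjamini-Hochberg step at rate `Q` flags the outliers. Points on an
#' exact line are never removed, and `Q = 0` removes nothing.
#'
#' @param x,y paired observations (>= 4 points).
#' @param Q maximum false discovery rate (default 0.0005, i.e. 0.05%).
#' @param method `"fdr_robust"` or `"none"`.
#' @return list with `kept` and `removed` (integer indices), `coefficients`
#'   of the robust line.
#' @export
remove_outliers <- function(x, y, Q = 0.0005, method = c("fdr_robust",
                                                         "none")) {
  method <- match.arg(method)
  n <- length(x)
  if (n < 4) stop("need at least 4 points")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  if (Q < 0 || Q > 1) stop("Q must lie in [0, 1]")
  if (method == "none" || Q == 0)
    return(list(kept = seq_len(n), removed = integer(0),
                coefficients = coef(lm(y ~ x))))
  # LAD by IRLS
  w <- rep(1, n)
  beta <- coef(lm(y ~ x))
  for (it in 1:50) {
    fit <- lm(y ~ x, weights = w)
    nb <- coef(fit)
    if (max(abs(nb - beta)) < 1e-10 * (1 + max(abs(beta)))) { beta <- nb; break }
    beta <- nb
    r <- abs(y - beta[1] - beta[2] * x)
    w <- 1 / pmax(r, 1e-8 * max(r, 1e-300))
  }
  r <- y - beta[1] - beta[2] * x
  scale <- quantile(abs(r), 0.6827, names = FALSE)
  if (scale == 0) {
    removed <- which(abs(r) > 0)
    if (!length(removed))
      return(list(kept = seq_len(n), removed = integer(0),
                  coefficients = beta))
    return(list(kept = setdiff(seq_len(n), removed), removed = removed,
                coefficients = beta))
  }
  tstat <- abs(r) / scale
  p <- 2 * pt(-tstat, df = n - 2)
  ordp <- order(p)
  thresh <- Q * seq_len(n) / n
  ok <- p[ordp] <= thresh
  kmax <- if (any(ok)) max(which(ok)) else 0L
  removed <- if (kmax > 0) sort(ordp[seq_len(kmax)]) else integer(0)
  list(kept = setdiff(seq_len(n), removed), removed = removed,
       coefficients = beta)
}

#' Murray's-law regression over bifurcation records
#'
#' Murray's law states that at an energy-optimal bifurcation the cube of
#' the parent radius equals the sum of the cubed child radii. Each record
#' contributes `x = (sum r_i^3)^(1/3)` and `y = r_parent`; after robust
#' FDR outlier removal an ordinary least-squares line is fitted. The
#' theoretical law is the identity line (slope 1, intercept 0) in any
#' units. `on_cubes = TRUE` instead regresses `y^3` on `sum r_i^3`.
#'
#' @param records [extract_bifurcations()] output.
#' @param unit_scale factor applied to radii before fitting (default 1e-6:
#'   micrometres to metres, the scale on which organ-level intercepts are
#'   conventionally reported).
#' @param Q outlier-removal FDR (see [remove_outliers()]); `NA` disables
#'   removal.
#' @param exponent bifurcation exponent (default 3).
#' @param on_cubes regress cubed radii instead of radii.
#' @return A `murray_fit` list: `slope`, `intercept`, `r2`, `n_points`,
#'   `n_outliers_removed`, `x`, `y` (post-removal, scaled), `ss_about_fit`,
#'   `ss_about_murray` (residual sums of squares about the fitted line and
#'   the theoretical identity line).
#' @export
murray_regression <- function(records, unit_scale = 1e-6, Q = 0.0005,
                              exponent = 3, on_cubes = FALSE) {
  if (!nrow(records)) stop("no bifurcation records")
  xs <- vapply(records$child_radii,
               function(r) sum(r^exponent)^(1 / exponent), 0)
  ys <- records$parent_radius
  x <- xs * unit_scale; y <- ys * unit_scale
  if (on_cubes) { x <- x^exponent; y <- y^exponent }
  removed <- integer(0)
  if (!is.na(Q) && Q > 0 && length(x) >= 4) {
    ro <- remove_outliers(x, y, Q = Q)
    removed <- ro$removed
    x <- x[ro$kept]; y <- y[ro$kept]
  }
  if (length(x) < 3) stop("fewer than 3 records after outlier removal")
  fit <- lm(y ~ x)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r2 = r_squared(fit),
                 n_points = length(x),
                 n_outliers_removed = length(removed),
                 x = x, y = y,
                 ss_about_fit = sum(fit$residuals^2),
                 ss_about_murray = sum((y - x)^2)),
            class = "murray_fit")
}

#' @export
print.murray_fit <- function(x, ...) {
  cat(sprintf("Murray regression: slope %.3f, intercept %.3g, R^2 %.3f (n = %d, %d outliers removed)\n",
              x$slope, x$intercept, x$r2, x$n_points,
              x$n_outliers_removed))
  invisible(x)
}

#' Extra sum-of-squares F test between nested models
#'
#' Tests whether the simpler (null) model fits as well as the more
#' flexible (alternative) model:
#' `F = ((ss_null - ss_alt) / (df_null - df_alt)) / (ss_alt / df_alt)`,
#' with the p-value from the upper tail of the F distribution.
#'
#' @param ss_null,ss_alt residual sums of squares (`ss_null >= ss_alt`).
#' @param df_null,df_alt residual degrees of freedom
#'   (`df_null > df_alt >= 1`).
#' @return list `F`, `df_num`, `df_den`, `p`.
#' @export
extra_ss_ftest <- function(ss_null, df_null, ss_alt, df_alt) {
  if (df_alt < 1 || df_null <= df_alt) stop("need df_null > df_alt >= 1")
  if (ss_alt < 0 || ss_null < ss_alt - 1e-12 * max(1, ss_null))
    stop("need ss_null >= ss_alt >= 0")
  dfn <- df_null - df_alt
  Fv <- ((ss_null - ss_alt) / dfn) / (ss_alt / df_alt)
  # numerically identical models (self-comparison) differ only by
  # floating-point noise in the residual sums
  if (!is.finite(Fv) || Fv < 0 ||
      ss_null - ss_alt <= 1e-12 * max(ss_null, 1e-300)) Fv <- 0
  list(F = Fv, df_num = dfn, df_den = df_alt,
       p = pf(Fv, dfn, df_alt, lower.tail = FALSE))
}

#' Compare radius scaling between two datasets
#'
#' Normalises each dataset's per-order mean radii to its value at a
#' reference order, fits `ln(normalised radius)` against order per
#' dataset and globally, and tests (extra sum-of-squares F, two
#' constrained parameters) whether a single slope and intercept fit both.
#'
#' @param a,b data.frames with `order` and `radius` (mean radius per
#'   Strahler order).
#' @param ref_order reference order for normalisation (default 9; both
#'   datasets must cover it).
#' @return list with `fit_a`, `fit_b`, `fit_global` (lm objects),
#'   `normalised` (stacked data) and `ftest`.
#' @export
compare_scaling <- function(a, b, ref_order = 9) {
  norm1 <- function(d, nm) {
    ref <- d$radius[d$order == ref_order]
    if (!length(ref)) stop("dataset '", nm, "' does not cover the reference order")
    data.frame(dataset = nm, order = d$order, lnr = log(d$radius / ref[1]))
  }
  da <- norm1(a, "a"); db <- norm1(b, "b")
  fa <- lm(lnr ~ order, da); fb <- lm(lnr ~ order, db)
  pooled <- rbind(da, db)
  fg <- lm(lnr ~ order, pooled)
  ss_alt <- sum(fa$residuals^2) + sum(fb$residuals^2)
  ss_null <- sum(fg$residuals^2)
  # residual sums that are pure floating-point noise relative to the data
  # variance (exact fits, identical datasets) are treated as zero
  tot <- sum((pooled$lnr - mean(pooled$lnr))^2)
  if (ss_null <= 1e-20 * tot) ss_null <- 0
  if (ss_alt <= 1e-20 * tot) ss_alt <- 0
  n <- nrow(pooled)
  ft <- extra_ss_ftest(ss_null, n - 2, ss_alt, n - 4)
  list(fit_a = fa, fit_b = fb, fit_global = fg, normalised = pooled,
       ftest = ft)
}

#' Extrapolate additional Strahler orders from terminal counts
#'
#' Given the number of imaged terminal segments, a target terminal count
#' (e.g. a glomerular number estimate) and the branching ratio, estimates
#' how many further orders lie below the imaging resolution:
#' `round(ln(n_target / n_terminal) / ln(gamma))`, clipped at 0.
#'
#' @param n_terminal,n_target counts (>= 1).
#' @param gamma branching ratio (> 1).
#' @return integer number of additional orders.
#' @export
extrapolate_orders <- function(n_terminal, n_target, gamma) {
  if (gamma <= 1) stop("gamma must exceed 1")
  if (n_terminal < 1 || n_target < 1) stop("counts must be >= 1")
  max(0L, as.integer(round(log(n_target / n_terminal) / log(gamma))))
}
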