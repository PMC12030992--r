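#' Discretize a continuous factor into strata
#'
#' Four classification methods for turning a continuous driving factor into
#' the strata a geographical detector needs:
#' \describe{
#'   \item{equal_interval}{k equal-width bins over `[min, max]`.}
#'   \item{quantile}{k equal-count bins by order statistics.}
#'   \item{geometric}{bin widths in geometric progression spanning the data
#'     range; the common ratio is solved numerically to balance class counts,
#'     widening bins toward the long tail (ratio > 1 under right skew,
#'     < 1 under left skew).}
#'   \item{std_dev}{breaks at the mean plus multiples of half a standard
#'     deviation, symmetric around the mean, truncated to k classes.}
#' }
#' Empty bins are merged with their nearest non-empty neighbour, so the
#' returned stratum count can be below `k`.
#'
#' @param values numeric vector (no `NA`s).
#' @param method one of `"equal_interval"`, `"quantile"`, `"geometric"`,
#'   `"std_dev"`.
#' @param k target number of strata (>= 2).
#' @return list with integer `labels` (1..L per value), `method`, `k`,
#'   `breaks`, `L` (effective stratum count); class `strata_partition`.
#' @examples
#' discretize(1:8, "quantile", 4)$labels
#' @export
discretize <- function(values, method = c("equal_interval", "quantile",
                                          "geometric", "std_dev"), k = 4) {
  method <- match.arg(method)
  stopifnot(k >= 2)
  x <- as.numeric(values)
  if (anyNA(x)) stop("values must not contain NA")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant column: a single stratum explains nothing")
  breaks <- switch(method,
    equal_interval = seq(rng[1], rng[2], length.out = k + 1)[2:k],
    quantile = {
      if (length(unique(x)) < k)
        stop("quantile method needs at least k distinct values")
      unique(stats::quantile(x, seq_len(k - 1) / k, names = FALSE, type = 7))
    },
    geometric = geometric_breaks(x, k),
    std_dev = {
      b <- mean(x) + 0.5 * stats::sd(x) * (seq_len(k - 1) - k / 2)
      b[b > rng[1] & b < rng[2]]
    })
  labels <- findInterval(x, sort(unique(breaks))) + 1L
  labels <- merge_empty_strata(labels)
  structure(list(labels = labels, method = method, k = as.integer(k),
                 breaks = sort(unique(breaks)), L = max(labels)),
            class = "strata_partition")
}

# Geometric-interval breaks: widths w, w*r, ..., w*r^(k-1) summing to the
# data range. r is searched over ratios (direction set by the skew sign) to
# minimize the variance of class counts; this package's own definition.
geometric_breaks <- function(x, k) {
  rng <- range(x)
  span <- diff(rng)
  sk <- mean((x - mean(x))^3) / (stats::sd(x)^3 * (1 - 1 / length(x))^1.5)
  if (!is.finite(sk)) sk <- 0
  interval <- if (sk >= 0) c(1, 10) else c(0.1, 1)
  counts_var <- function(r) {
    w1 <- if (abs(r - 1) < 1e-12) span / k else span * (r - 1) / (r^k - 1)
    br <- rng[1] + w1 * cumsum(r^(0:(k - 2)))
    lab <- findInterval(x, br) + 1L
    stats::var(tabulate(lab, k))
  }
  r <- stats::optimize(counts_var, interval)$minimum
  # prefer r = 1 (equal widths) when it does at least as well
  if (counts_var(1) <= counts_var(r) + 1e-12) r <- 1
  w1 <- if (abs(r - 1) < 1e-12) span / k else span * (r - 1) / (r^k - 1)
  rng[1] + w1 * cumsum(r^(0:(k - 2)))
}

# Relabel so that strata with no members disappear and labels are 1..L.
merge_empty_strata <- function(labels) {
  present <- sort(unique(labels))
  as.integer(match(labels, present))
}

#' Factor detector q statistic
#'
#' Explanatory power of a stratification for a response:
#' q = 1 - SSW/SST = 1 - sum_h N_h sigma_h^2 / (N sigma^2), with population
#' (N-denominator) variances. q = 1 when strata are internally constant,
#' q = 0 when the stratification explains nothing.
#'
#' @param y numeric response per unit.
#' @param strata a `strata_partition`, or an integer/factor vector of stratum
#'   labels.
#' @return q in `[0, 1]`.
#' @examples
#' factor_q(c(1, 2, 3, 4), c(1, 1, 2, 2))  # 0.8
#' @export
factor_q <- function(y, strata) {
  h <- strata_labels(strata)
  stopifnot(length(y) == length(h))
  ok <- !is.na(y) & !is.na(h)
  y <- y[ok]; h <- h[ok]
  n <- length(y)
  if (length(unique(h)) < 2) stop("need at least 2 non-empty strata")
  sst <- n * pop_var(y)
  if (sst == 0) stop("SST is zero: q undefined")
  ssw <- sum(vapply(split(y, h), function(g) length(g) * pop_var(g),
                    numeric(1)))
  1 - ssw / sst
}

pop_var <- function(x) mean((x - mean(x))^2)

strata_labels <- function(strata) {
  if (inherits(strata, "strata_partition")) return(strata$labels)
  if (is.factor(strata)) return(as.integer(strata))
  as.integer(strata)
}

#' Interaction detector
#'
#' Overlays two stratifications (cross-tabulation of their labels, empty
#' cells dropped), computes q of the overlay, and types the interaction:
#' \itemize{
#'   \item nonlinear-weaken: q12 < min(q1, q2)
#'   \item uni-variable-weaken: min <= q12 <= max
#'   \item bivariable-enhanced: max < q12 < q1 + q2
#'   \item independent: q12 = q1 + q2 (within `tol`)
#'   \item nonlinear-enhanced: q12 > q1 + q2
#' }
#' Boundary equalities are resolved by exact comparison with tolerance `tol`;
#' q12 equal to the larger single q falls on the uni-variable-weaken side.
#'
#' @param y numeric response.
#' @param strata1,strata2 stratifications (see [factor_q()]).
#' @param tol equality tolerance (default 1e-9).
#' @return list with `q12`, `q1`, `q2`, `type`.
#' @export
interaction_q <- function(y, strata1, strata2, tol = 1e-9) {
  h1 <- strata_labels(strata1); h2 <- strata_labels(strata2)
  q1 <- factor_q(y, h1); q2 <- factor_q(y, h2)
  overlay <- as.integer(interaction(h1, h2, drop = TRUE))
  if (length(unique(overlay)) < 2)
    stop("overlay collapses to one stratum")
  q12 <- factor_q(y, overlay)
  list(q12 = q12, q1 = q1, q2 = q2,
       type = interaction_type(q1, q2, q12, tol))
}

# Interaction typing rule, factored out so the boundary conventions are
# testable in isolation.
interaction_type <- function(q1, q2, q12, tol = 1e-9) {
  lo <- min(q1, q2); hi <- max(q1, q2)
  if (abs(q12 - (q1 + q2)) <= tol) "Independent"
  else if (q12 > q1 + q2) "Nonlinear-enhanced"
  else if (q12 > hi + tol) "Bivariable-enhanced"
  else if (q12 < lo - tol) "Nonlinear-weaken"
  else "Uni-variable-weaken"
}

#' Risk detector
#'
#' Stratum means of the response and, for every stratum pair with at least 2
#' units each, a Welch two-sample t test of the mean difference
#' (Welch-Satterthwaite degrees of freedom, two-sided). Also reports the
#' stratum with the highest mean - the factor's optimal range.
#'
#' @param y numeric response.
#' @param strata stratification (see [factor_q()]).
#' @param alpha significance level (default 0.05).
#' @return list with `means` (data.frame stratum/n/mean), `sig` (logical
#'   matrix, `NA` where a stratum was too small), `t` (t statistics),
#'   `best_stratum`.
#' @export
risk_detect <- function(y, strata, alpha = 0.05) {
  h <- strata_labels(strata)
  groups <- split(y, h)
  L <- length(groups)
  means <- data.frame(stratum = as.integer(names(groups)),
                      n = vapply(groups, length, integer(1)),
                      mean = vapply(groups, mean, numeric(1)))
  rownames(means) <- NULL
  sig <- matrix(NA, L, L, dimnames = list(names(groups), names(groups)))
  tmat <- matrix(NA_real_, L, L, dimnames = dimnames(sig))
  for (a in seq_len(L - 1)) for (b in (a + 1):L) {
    ga <- groups[[a]]; gb <- groups[[b]]
    if (length(ga) < 2 || length(gb) < 2) next
    if (stats::sd(ga) == 0 && stats::sd(gb) == 0) {
      tt <- list(statistic = if (mean(ga) == mean(gb)) 0 else Inf,
                 p.value = if (mean(ga) == mean(gb)) 1 else 0)
    } else {
      tt <- stats::t.test(ga, gb, var.equal = FALSE)
    }
    tmat[a, b] <- tmat[b, a] <- unname(tt$statistic)
    sig[a, b] <- sig[b, a] <- tt$p.value < alpha
  }
  list(means = means, sig = sig, t = tmat,
       best_stratum = means$stratum[which.max(means$mean)])
}

#' Ecological detector
#'
#' Compares the within-strata variance sums of two factors on the same units
#' with the F ratio F = N1 (N2 - 1) SSW1 / (N2 (N1 - 1) SSW2) (N1 = N2 = N
#' here), referred to an F distribution with (N1 - 1, N2 - 1) degrees of
#' freedom. Significance means the two factors differ in how well they
#' stratify the response; the factor with the smaller SSW explains more.
#'
#' @param y numeric response.
#' @param strata1,strata2 stratifications on the same units.
#' @param alpha significance level (default 0.05).
#' @return list with `f`, `p`, `significant`.
#' @export
ecological_detect <- function(y, strata1, strata2, alpha = 0.05) {
  h1 <- strata_labels(strata1); h2 <- strata_labels(strata2)
  stopifnot(length(y) == length(h1), length(y) == length(h2))
  n <- length(y)
  ssw <- function(h) sum(vapply(split(y, h), function(g)
    length(g) * pop_var(g), numeric(1)))
  ssw1 <- ssw(h1); ssw2 <- ssw(h2)
  if (ssw2 == 0) stop("SSW of the second factor is zero: F undefined")
  f <- (n * (n - 1) * ssw1) / (n * (n - 1) * ssw2)  # N1 = N2 = n
  # one-sided: is factor 2's stratification significantly tighter (SSW1 >
  # SSW2)? Tested symmetrically by taking the larger ratio.
  fmax <- max(f, 1 / f)
  p <- 1 - stats::pf(fmax, n - 1, n - 1)
  list(f = f, p = p, significant = p < alpha)
}

#' Optimal discretization of a continuous factor
#'
#' Scans discretization methods and stratum counts, returning the partition
#' maximizing the factor detector's q. Ties prefer fewer strata, then the
#' method order given. Candidates that degenerate (constant column, too few
#' distinct values) are skipped.
#'
#' @param y numeric response.
#' @param values continuous factor values.
#' @param methods methods to try (default all four).
#' @param k_range stratum counts to try (default 4:8).
#' @return list with `partition` (best `strata_partition`), `q`, and the
#'   full `scan` data.frame.
#' @export
optimal_discretization <- function(y, values,
                                   methods = c("equal_interval", "quantile",
                                               "geometric", "std_dev"),
                                   k_range = 4:8) {
  grid <- expand.grid(k = sort(k_range), method = methods,
                      stringsAsFactors = FALSE)
  best <- NULL; best_q <- -Inf
  qs <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    part <- tryCatch(discretize(values, grid$method[i], grid$k[i]),
                     error = function(e) NULL)
    if (is.null(part) || part$L < 2) next
    q <- tryCatch(factor_q(y, part), error = function(e) NA_real_)
    qs[i] <- q
    if (!is.na(q) && q > best_q + 1e-12) { best <- part; best_q <- q }
  }
  if (is.null(best)) stop("all discretization candidates degenerate")
  list(partition = best, q = best_q,
       scan = cbind(grid, q = qs))
}

#' Run the full geographical detector on a factor table
#'
#' Continuous factors are discretized by [optimal_discretization()];
#' categorical factors (R factors or character columns) are used with their
#' native classes. Runs the factor detector on every factor, the interaction
#' detector on every unordered pair, and the risk and ecological detectors.
#'
#' @param table data.frame with a response column `y` and factor columns.
#' @param factors names of factor columns; default every column except
#'   `y`, `unit_id` and `zone`.
#' @param categorical names of factors to treat as categorical; default the
#'   non-numeric columns.
#' @param k_range,methods passed to [optimal_discretization()].
#' @param alpha significance level for risk/ecological detectors.
#' @return list with `q` (named, sorted descending), `interactions`
#'   (data.frame: factor1, factor2, q1, q2, q12, type), `risk` (per factor),
#'   `ecological` (data.frame per pair), `partitions`.
#' @export
run_geodetector <- function(table, factors = NULL, categorical = NULL,
                            k_range = 4:8,
                            methods = c("equal_interval", "quantile",
                                        "geometric", "std_dev"),
                            alpha = 0.05) {
  stopifnot(is.data.frame(table), "y" %in% names(table))
  if (is.null(factors))
    factors <- setdiff(names(table), c("y", "unit_id", "zone"))
  if (length(factors) < 2) stop("need at least 2 factors")
  table <- table[!is.na(table$y), , drop = FALSE]
  if (is.null(categorical))
    categorical <- factors[!vapply(table[factors], is.numeric, logical(1))]
  parts <- list()
  for (f in factors) {
    col <- table[[f]]
    parts[[f]] <- if (f %in% categorical) {
      lab <- as.integer(factor(col))
      structure(list(labels = lab, method = "native", k = max(lab),
                     breaks = numeric(), L = max(lab)),
                class = "strata_partition")
    } else {
      optimal_discretization(table$y, col, methods, k_range)$partition
    }
  }
  qv <- vapply(parts, function(p) factor_q(table$y, p), numeric(1))
  qv <- sort(qv, decreasing = TRUE)
  pairs <- utils::combn(factors, 2)
  inter <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    f1 <- pairs[1, j]; f2 <- pairs[2, j]
    r <- interaction_q(table$y, parts[[f1]], parts[[f2]])
    data.frame(factor1 = f1, factor2 = f2, q1 = r$q1, q2 = r$q2,
               q12 = r$q12, type = r$type, stringsAsFactors = FALSE)
  }))
  risk <- lapply(parts, function(p) risk_detect(table$y, p, alpha))
  eco <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    f1 <- pairs[1, j]; f2 <- pairs[2, j]
    r <- ecological_detect(table$y, parts[[f1]], parts[[f2]], alpha)
    data.frame(factor1 = f1, factor2 = f2, f = r$f, p = r$p,
               significant = r$significant, stringsAsFactors = FALSE)
  }))
  list(q = qv, interactions = inter, risk = risk, ecological = eco,
       partitions = parts)
}

#' Per-zone geographical detector with top interactions
#'
#' Runs [run_geodetector()] inside each zone of a factor table and reports,
#' per zone, the top-k interaction partners of a designated anchor factor by
#' overlay q. Zones with fewer than `min_units` units are skipped with a
#' warning.
#'
#' @param table data.frame with columns `y`, `zone`, and factors.
#' @param anchor anchor factor name (e.g. land use); `NULL` ranks all pairs.
#' @param top_k how many top interactions per zone (default 3).
#' @param min_units minimum units per zone (default 30).
#' @param ... passed to [run_geodetector()].
#' @return list with `zones` (named list of detector results) and
#'   `top_interactions` (data.frame: zone, partner, q12, type, rank).
#' @export
zonal_geodetector <- function(table, anchor = NULL, top_k = 3,
                              min_units = 30, ...) {
  stopifnot(is.data.frame(table), "zone" %in% names(table))
  zs <- sort(unique(table$zone))
  zones <- list(); tops <- list()
  for (z in zs) {
    sub <- table[table$zone == z, setdiff(names(table), "zone"),
                 drop = FALSE]
    if (nrow(sub) < min_units) {
      warning(sprintf("zone %s skipped: %d < %d units", z, nrow(sub),
                      min_units))
      next
    }
    res <- run_geodetector(sub, ...)
    zones[[as.character(z)]] <- res
    it <- res$interactions
    if (!is.null(anchor))
      it <- it[it$factor1 == anchor | it$factor2 == anchor, , drop = FALSE]
    it <- it[order(-it$q12), , drop = FALSE]
    it <- utils::head(it, top_k)
    if (nrow(it) > 0) {
      partner <- if (is.null(anchor)) paste(it$factor1, it$factor2, sep = ":")
                 else ifelse(it$factor1 == anchor, it$factor2, it$factor1)
      tops[[as.character(z)]] <- data.frame(
        zone = z, partner = partner, q12 = it$q12, type = it$type,
        rank = seq_len(nrow(it)), stringsAsFactors = FALSE)
    }
  }
  list(zones = zones, top_interactions = do.call(rbind, tops))
}
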