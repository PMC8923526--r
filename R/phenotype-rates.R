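#' Anthesis rates from cumulative flower counts
#'
#' Converts a cumulative-anthesis series into per-interval rates: the
#' gradient of the straight line between neighboring observation dates,
#' expressed in flowers per week (7-day units).
#'
#' @param series Data frame with columns `group`, `date` (coercible with
#'   [as.Date()]), and `cumulative_count` (nondecreasing within group).
#' @return Data frame of class `rate_table` with columns `group`, `start`,
#'   `end` and `rate`; one row per consecutive date pair, the interval being
#'   `(start, end]`.
#' @export
#' @examples
#' s <- data.frame(group = "A", date = as.Date("2016-08-01") + c(0, 7, 14),
#'                 cumulative_count = c(0, 7, 14))
#' anthesis_rates(s) # two intervals at 7 flowers/week
anthesis_rates <- function(series) {
  stopifnot(all(c("group", "date", "cumulative_count") %in% names(series)))
  series$date <- as.Date(series$date)
  out <- do.call(rbind, lapply(split(series, series$group), function(g) {
    g <- g[order(g$date), ]
    if (nrow(g) < 2) stop("group ", g$group[1], ": need at least 2 dates")
    if (anyDuplicated(g$date)) stop("group ", g$group[1], ": duplicate dates")
    if (any(diff(g$cumulative_count) < 0))
      stop("group ", g$group[1], ": cumulative counts must be nondecreasing")
    data.frame(group = g$group[1],
               start = utils::head(g$date, -1),
               end = g$date[-1],
               rate = diff(g$cumulative_count) /
                 (as.numeric(diff(g$date), units = "days") / 7))
  }))
  rownames(out) <- NULL
  class(out) <- c("rate_table", "data.frame")
  out
}

#' Pair interval rates with leaf samples
#'
#' Each sample receives the rate of the interval `(start, end]` of its group
#' that contains its sampling datetime; a sample dated exactly on an interval
#' boundary takes the interval ending on that date.
#'
#' @param rates A `rate_table` from [anthesis_rates()]. Its `group` values
#'   must be the `group_cols` of the metadata pasted with `sep`.
#' @param sample_meta Data frame with a `datetime` column plus `group_cols`.
#' @param group_cols Metadata columns identifying the rate group.
#' @param sep Separator used when pasting `group_cols` into the group key.
#' @return Numeric vector of per-sample rates (flowers per week).
#' @export
assign_rates_to_samples <- function(rates, sample_meta,
                                    group_cols = c("experiment", "cultivar"),
                                    sep = ":") {
  key <- do.call(paste, c(sample_meta[group_cols], sep = sep))
  dates <- as.Date(as.POSIXct(sample_meta$datetime, tz = "UTC"))
  y <- rep(NA_real_, nrow(sample_meta))
  for (i in seq_along(y)) {
    r <- rates[rates$group == key[i] & rates$start < dates[i] &
                 dates[i] <= rates$end, ]
    if (nrow(r) == 1) y[i] <- r$rate
  }
  if (anyNA(y))
    stop("sample(s) outside all rate intervals: ",
         paste(utils::head(sample_meta$sample_id[is.na(y)] %||%
                             which(is.na(y)), 10), collapse = ", "))
  y
}

midranks <- function(x) rank(x, ties.method = "average")

#' Mann-Whitney U test
#'
#' Rank-sum test for two independent groups. `U` is computed from midranks;
#' the two-sided p-value comes from exact enumeration of all group
#' assignments when both groups have at most `exact_max` observations
#' (handles ties naturally), otherwise from the normal approximation with
#' tie correction.
#'
#' @param a,b Numeric vectors (anthesis rates of the two groups).
#' @param exact_max Largest group size for which the exact distribution is
#'   enumerated.
#' @return List with `U_a`, `U_b`, `statistic` (= `U_a`), `p_value`,
#'   `method`.
#' @export
mann_whitney_u <- function(a, b, exact_max = 8) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  na <- length(a); nb <- length(b); n <- na + nb
  r <- midranks(c(a, b))
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (na <= exact_max && nb <= exact_max) {
    sets <- combn(n, na)
    rsums <- colSums(matrix(r[sets], nrow = na))
    us <- rsums - na * (na + 1) / 2
    p <- mean(abs(us - mu) >= abs(u_a - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- na * nb / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_a - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation with tie correction"
  }
  list(U_a = u_a, U_b = na * nb - u_a, statistic = u_a,
       p_value = min(p, 1), method = method)
}

#' Kruskal-Wallis test with Conover-Iman pairwise comparisons
#'
#' The omnibus H statistic (with tie correction) is computed via
#' [stats::kruskal.test()]; pairwise group differences are then assessed
#' with Conover's t statistic
#' `t = (Rbar_a - Rbar_b) / sqrt(S^2 * ((N-1-H)/(N-k)) * (1/n_a + 1/n_b))`
#' where `S^2` is the variance of all midranks, referred to a Student t
#' distribution with `N - k` degrees of freedom (two-sided).
#'
#' @param groups Named list of at least three numeric vectors, each with at
#'   least two observations.
#' @param p_adjust Multiple-testing adjustment for the pairwise p-values
#'   (any method of [stats::p.adjust()]; default `"none"`, reported
#'   unadjusted).
#' @return List with `H`, `p_value`, `df`, and a `pairwise` data frame
#'   (`group_a`, `group_b`, `t`, `p`).
#' @export
kruskal_wallis_conover <- function(groups, p_adjust = "none") {
  if (length(groups) < 3)
    stop("need at least 3 groups; use mann_whitney_u() for two")
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 values")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- kruskal.test(groups)
  H <- unname(kw$statistic)
  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x); k <- length(groups)
  r <- midranks(x)
  rbar <- tapply(r, g, mean)
  nj <- lengths(groups)[names(rbar)]
  s2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  pairs <- combn(names(groups), 2)
  tstat <- pval <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    ga <- pairs[1, p]; gb <- pairs[2, p]
    se <- sqrt(s2 * ((N - 1 - H) / (N - k)) * (1 / nj[ga] + 1 / nj[gb]))
    tstat[p] <- (rbar[ga] - rbar[gb]) / se
    pval[p] <- 2 * pt(-abs(tstat[p]), df = N - k)
  }
  pval <- stats::p.adjust(pval, method = p_adjust)
  list(H = H, p_value = unname(kw$p.value), df = unname(kw$parameter),
       pairwise = data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
                             t = tstat, p = pmin(pval, 1)))
}
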