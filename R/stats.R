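#' Cycle plans: statistics as sequences of secure sums
#'
#' Each supported statistic is expressed as a `cycle_plan`: an ordered list
#' of secure-summation cycles (each cycle is one full execution of the
#' two-round protocol over a fixed set of variables), local pre-processing
#' between cycles, and a final local computation on the pooled sums. All
#' any party ever learns are the planned global sums of each cycle — never
#' another party's local values.
#'
#' Cycle counts per method: frequency, chi-square, quartiles, Wilcoxon and
#' mean need 1 cycle; standard deviation and t-test/ANOVA need 2 (the
#' global means from cycle 1 are public to every party by protocol design,
#' so each party centers its own data locally for cycle 2 without extra
#' messages); Pearson correlation needs 3 (means, then sums of squares,
#' then the cross-product sum).
#'
#' @param method Method tag.
#' @param cycles List of cycle specs (`vars`, `inputs(data, ctx)`).
#' @param finalizer `function(pooled, ctx)` returning the named statistics.
#' @return A `cycle_plan` object with `n_cycles = length(cycles)`.
#' @seealso [run_plan()], [plan_frequency()], [plan_mean()]
#' @export
cycle_plan <- function(method, cycles, finalizer) {
  structure(list(method = method, cycles = cycles, finalizer = finalizer,
                 n_cycles = length(cycles)),
            class = "cycle_plan")
}

#' @export
print.cycle_plan <- function(x, ...) {
  cat(sprintf("<cycle_plan> %s: %d cycle(s)\n", x$method, x$n_cycles))
  invisible(x)
}

# align party data onto a fixed class list as non-negative integer counts;
# accepts raw values, a named count vector, or a data.frame(class, count)
normalize_counts <- function(data, classes, what = "data") {
  if (is.data.frame(data)) {
    if (!all(c("class", "count") %in% names(data)))
      abort_ss("securesum_stats_error", "%s: expected columns class, count", what)
    counts <- stats::setNames(as.numeric(data$count), as.character(data$class))
  } else if (!is.null(names(data))) {
    counts <- stats::setNames(as.numeric(data), names(data))
  } else {
    vals <- as.character(data)
    if (any(!vals %in% classes))
      abort_ss("securesum_stats_error", "%s: value(s) outside the declared classes: %s",
               what, paste(unique(setdiff(vals, classes)), collapse = ", "))
    tab <- table(factor(vals, levels = classes))
    counts <- stats::setNames(as.numeric(tab), names(tab))
  }
  if (any(!names(counts) %in% classes))
    abort_ss("securesum_stats_error", "%s: unknown class(es): %s", what,
             paste(setdiff(names(counts), classes), collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts)))
    abort_ss("securesum_stats_error", "%s: counts must be non-negative integers", what)
  out <- stats::setNames(numeric(length(classes)), classes)
  out[names(counts)] <- counts
  out
}

# round a local derived input onto the fixed-point grid and render it as an
# exact decimal literal for encoding
fp_grid <- function(x, ring) {
  sprintf(paste0("%.", ring$scale_digits, "f"), round(x, ring$scale_digits))
}

#' Frequency distribution plan (1 cycle)
#'
#' Parties contribute local frequencies per class of a nominal variable;
#' the pooled result is the global frequency distribution.
#'
#' @param classes Character vector of class labels (>= 1), fixed a priori.
#' @return A [cycle_plan()].
#' @export
plan_frequency <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 1L)
    abort_ss("securesum_stats_error", "at least one class is required")
  cycle_plan(
    "FREQUENCY",
    list(list(vars = classes,
              inputs = function(data, ctx) normalize_counts(data, classes))),
    finalizer = function(pooled, ctx) list(counts = pooled[[1]])
  )
}

#' Chi-square statistic from a pooled contingency table
#'
#' Pearson's statistic `sum((O - E)^2 / E)` with expected counts from the
#' row/column margins of the pooled table; `df = (r - 1)(c - 1)`.
#'
#' @param pooled_cells Numeric matrix (>= 2x2) of pooled counts.
#' @return List with `chi_square` and `df`.
#' @export
chi_square_from_counts <- function(pooled_cells) {
  o <- as.matrix(pooled_cells)
  if (nrow(o) < 2L || ncol(o) < 2L)
    abort_ss("securesum_stats_error", "contingency table must be at least 2x2")
  rs <- rowSums(o); cs <- colSums(o)
  if (any(rs == 0) || any(cs == 0))
    abort_ss("securesum_stats_error", "zero row or column margin in the pooled table")
  e <- outer(rs, cs) / sum(o)
  list(chi_square = sum((o - e)^2 / e),
       df = (nrow(o) - 1L) * (ncol(o) - 1L))
}

#' Chi-square test plan (1 cycle)
#'
#' The cells of the contingency table are defined a priori; local cell
#' counts are pooled in one cycle and the statistic is computed from the
#' global table.
#'
#' @param rows,cols Row and column class labels.
#' @return A [cycle_plan()]. Party data: a rows-by-cols count matrix with
#'   matching dimnames (or plain, in the declared order).
#' @export
plan_chi_square <- function(rows, cols) {
  rows <- as.character(rows); cols <- as.character(cols)
  vars <- as.vector(outer(rows, cols, paste, sep = ":"))
  cycle_plan(
    "CHI_SQUARE",
    list(list(vars = vars, inputs = function(data, ctx) {
      m <- as.matrix(data)
      if (!all(dim(m) == c(length(rows), length(cols))))
        abort_ss("securesum_stats_error", "expected a %dx%d count matrix",
                 length(rows), length(cols))
      if (any(m < 0) || any(m != round(m)))
        abort_ss("securesum_stats_error", "cell counts must be non-negative integers")
      stats::setNames(as.vector(m), vars)
    })),
    finalizer = function(pooled, ctx) {
      tab <- matrix(pooled[[1]][vars], nrow = length(rows),
                    dimnames = list(rows, cols))
      chi_square_from_counts(tab)
    }
  )
}

#' Quartiles of a pooled ordinal frequency distribution
#'
#' Discrete inverse-empirical-CDF rule (quantile type 1): each quartile is
#' the smallest class whose cumulative relative frequency reaches the
#' target — ordinal classes admit no interpolation.
#'
#' @param pooled_freqs Named numeric vector of pooled counts, names in
#'   ordinal class order.
#' @return List with `q1`, `median`, `q3` (class labels).
#' @export
quartiles_from_freq <- function(pooled_freqs) {
  n <- sum(pooled_freqs)
  if (n < 1)
    abort_ss("securesum_stats_error", "empty pooled distribution")
  cum <- cumsum(pooled_freqs) / n
  pick <- function(q) names(pooled_freqs)[which(cum >= q - 1e-12)[1]]
  list(q1 = pick(0.25), median = pick(0.5), q3 = pick(0.75))
}

#' Quartiles plan (1 cycle)
#'
#' @param classes Class labels in ordinal order.
#' @return A [cycle_plan()]. Party data: raw values, a named count vector,
#'   or a `data.frame(class, count)`.
#' @export
plan_quartiles <- function(classes) {
  classes <- as.character(classes)
  if (length(classes) < 1L)
    abort_ss("securesum_stats_error", "at least one class is required")
  cycle_plan(
    "QUARTILES",
    list(list(vars = classes,
              inputs = function(data, ctx) normalize_counts(data, classes))),
    finalizer = function(pooled, ctx) quartiles_from_freq(pooled[[1]][classes])
  )
}

#' Wilcoxon rank-sum statistic from two pooled frequency tables
#'
#' Mann-Whitney U from grouped ordinal data using midranks for ties, with
#' the normal approximation using the tie-corrected variance. No
#' continuity correction by default.
#'
#' @param freqs_g1,freqs_g2 Pooled counts per class, same ordinal class
#'   order in both.
#' @param continuity Apply a 0.5 continuity correction to `z`.
#' @return List with `U` (for group 1), `z`, `n1`, `n2`.
#' @export
wilcoxon_rank_sum <- function(freqs_g1, freqs_g2, continuity = FALSE) {
  if (length(freqs_g1) != length(freqs_g2))
    abort_ss("securesum_stats_error", "groups must share one ordered class list")
  n1 <- sum(freqs_g1); n2 <- sum(freqs_g2); n <- n1 + n2
  if (n1 < 1 || n2 < 1)
    abort_ss("securesum_stats_error", "both groups must be non-empty")
  t_k <- freqs_g1 + freqs_g2
  midrank <- cumsum(t_k) - t_k + (t_k + 1) / 2
  r1 <- sum(freqs_g1 * midrank)
  u <- r1 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie <- sum(t_k^3 - t_k) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie)
  z <- if (v > 0) {
    num <- u - mu
    if (continuity) num <- num - sign(num) * 0.5
    num / sqrt(v)
  } else 0
  list(U = u, z = z, n1 = n1, n2 = n2)
}

#' Wilcoxon rank-sum plan (1 cycle)
#'
#' Both groups' class frequencies travel as variables of a single cycle,
#' yielding two pooled distributions from which the grouped-data U
#' statistic is computed.
#'
#' @param classes Class labels in ordinal order.
#' @param groups Two group labels (default `"group1"`, `"group2"`).
#' @param continuity Continuity correction flag, see [wilcoxon_rank_sum()].
#' @return A [cycle_plan()]. Party data: `data.frame(value, group)` with
#'   raw ordinal values, or `list(<g1> = counts, <g2> = counts)`.
#' @export
plan_wilcoxon <- function(classes, groups = c("group1", "group2"),
                          continuity = FALSE) {
  classes <- as.character(classes)
  if (length(groups) != 2L)
    abort_ss("securesum_stats_error", "exactly two groups are required")
  vars <- c(paste(groups[1], classes, sep = ":"),
            paste(groups[2], classes, sep = ":"))
  cycle_plan(
    "WILCOXON",
    list(list(vars = vars, inputs = function(data, ctx) {
      if (is.data.frame(data)) {
        counts <- lapply(groups, function(g)
          normalize_counts(data$value[data$group == g], classes, g))
      } else {
        counts <- lapply(groups, function(g)
          normalize_counts(data[[g]] %||% numeric(0), classes, g))
      }
      stats::setNames(c(counts[[1]], counts[[2]]), vars)
    })),
    finalizer = function(pooled, ctx) {
      f1 <- pooled[[1]][paste(groups[1], classes, sep = ":")]
      f2 <- pooled[[1]][paste(groups[2], classes, sep = ":")]
      wilcoxon_rank_sum(f1, f2, continuity = continuity)
    }
  )
}

#' Pooled mean plan (1 cycle)
#'
#' Each party contributes its local sum and local count; the global mean is
#' the pooled sum divided by the pooled count.
#'
#' @return A [cycle_plan()]. Party data: numeric vector of local values.
#' @export
plan_mean <- function() {
  cycle_plan(
    "MEAN",
    list(list(vars = c(".sum", ".count"), inputs = function(data, ctx) {
      x <- as.numeric(data)
      c(.sum = sum(x), .count = length(x))
    })),
    finalizer = function(pooled, ctx) {
      n <- pooled[[1]][[".count"]]
      if (n < 1) abort_ss("securesum_stats_error", "pooled count is zero")
      list(mean = pooled[[1]][[".sum"]] / n, n = n)
    }
  )
}

#' Pooled standard deviation plan (2 cycles)
#'
#' Cycle 1 pools sums and counts, making the global mean public to all
#' parties; in cycle 2 each party pools its local sum of squared deviations
#' from that global mean. The sample denominator `N - 1` is used,
#' consistent with the t-test/ANOVA convention.
#'
#' @param denominator `"n-1"` (sample, default) or `"n"` (population).
#' @return A [cycle_plan()]. Party data: numeric vector of local values.
#' @export
plan_sd <- function(denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  cycle_plan(
    "SD",
    list(
      list(vars = c(".sum", ".count"), inputs = function(data, ctx) {
        x <- as.numeric(data)
        c(.sum = sum(x), .count = length(x))
      }),
      list(vars = ".ss", inputs = function(data, ctx) {
        gm <- ctx$pooled[[1]][[".sum"]] / ctx$pooled[[1]][[".count"]]
        c(.ss = sum((as.numeric(data) - gm)^2))
      })
    ),
    finalizer = function(pooled, ctx) {
      n <- pooled[[1]][[".count"]]
      if (n < 2) abort_ss("securesum_stats_error", "pooled count must be >= 2")
      denom <- if (denominator == "n-1") n - 1 else n
      list(sd = sqrt(pooled[[2]][[".ss"]] / denom),
           mean = pooled[[1]][[".sum"]] / n, n = n)
    }
  )
}

#' One-way ANOVA / t-test plan (2 cycles)
#'
#' Cycle 1 pools per-group sums and counts (fixing the global group means
#' and grand mean); cycle 2 pools the within-group sums of squared
#' deviations of each party's data from its group's global mean. The
#' statistic is `F = (SSB / (k - 1)) / (SSW / (N - k))`; with two groups,
#' `t = sign(m1 - m2) * sqrt(F)` on `N - 2` degrees of freedom is also
#' reported (the t-test is the two-group special case).
#'
#' @param groups Character vector of k >= 2 group labels, fixed a priori.
#' @return A [cycle_plan()]. Party data: `data.frame(value, group)`.
#' @export
plan_anova <- function(groups) {
  groups <- as.character(groups)
  k <- length(groups)
  if (k < 2L) abort_ss("securesum_stats_error", "at least two groups are required")
  sum_vars <- paste(groups, "sum", sep = ":")
  cnt_vars <- paste(groups, "count", sep = ":")
  ss_vars <- paste(groups, "ss", sep = ":")
  split_groups <- function(data) {
    if (!is.data.frame(data) || !all(c("value", "group") %in% names(data)))
      abort_ss("securesum_stats_error", "expected data.frame(value, group)")
    if (any(!data$group %in% groups))
      abort_ss("securesum_stats_error", "unknown group label(s): %s",
               paste(unique(setdiff(data$group, groups)), collapse = ", "))
    lapply(groups, function(g) as.numeric(data$value[data$group == g]))
  }
  cycle_plan(
    "TTEST_ANOVA",
    list(
      list(vars = c(sum_vars, cnt_vars), inputs = function(data, ctx) {
        xs <- split_groups(data)
        stats::setNames(c(vapply(xs, sum, 0), vapply(xs, length, 0L)),
                        c(sum_vars, cnt_vars))
      }),
      list(vars = ss_vars, inputs = function(data, ctx) {
        xs <- split_groups(data)
        means <- ctx$pooled[[1]][sum_vars] / ctx$pooled[[1]][cnt_vars]
        stats::setNames(
          vapply(seq_len(k), function(i) sum((xs[[i]] - means[i])^2), 0),
          ss_vars)
      })
    ),
    finalizer = function(pooled, ctx) {
      ns <- pooled[[1]][cnt_vars]
      if (any(ns < 2))
        abort_ss("securesum_stats_error", "every group needs a pooled count >= 2")
      sums <- pooled[[1]][sum_vars]
      means <- sums / ns
      n <- sum(ns)
      grand <- sum(sums) / n
      ssb <- sum(ns * (means - grand)^2)
      ssw <- sum(pooled[[2]][ss_vars])
      f <- (ssb / (k - 1)) / (ssw / (n - k))
      out <- list(F = f, df1 = k - 1, df2 = n - k,
                  group_means = stats::setNames(as.numeric(means), groups))
      if (k == 2L) out$t <- sign(means[[1]] - means[[2]]) * sqrt(f)
      out
    }
  )
}

#' Pearson correlation plan (3 cycles)
#'
#' For horizontally partitioned paired data (every party holds both
#' variables for its own records): cycle 1 pools the sums of x and y and
#' the record count, cycle 2 the sums of squared deviations of each
#' variable from its global mean, cycle 3 the sum of cross-products. Then
#' \eqn{r = S_{xy} / \sqrt{SS_x SS_y}} (the N - 1 denominators cancel).
#'
#' @return A [cycle_plan()]. Party data: `data.frame(x, y)`.
#' @export
plan_correlation <- function() {
  need_xy <- function(data) {
    if (!is.data.frame(data) || !all(c("x", "y") %in% names(data)))
      abort_ss("securesum_stats_error", "expected data.frame(x, y) of paired values")
    data
  }
  means <- function(ctx) {
    n <- ctx$pooled[[1]][[".count"]]
    c(mx = ctx$pooled[[1]][["x:sum"]] / n, my = ctx$pooled[[1]][["y:sum"]] / n)
  }
  cycle_plan(
    "CORRELATION",
    list(
      list(vars = c("x:sum", "y:sum", ".count"), inputs = function(data, ctx) {
        d <- need_xy(data)
        c("x:sum" = sum(d$x), "y:sum" = sum(d$y), ".count" = nrow(d))
      }),
      list(vars = c("x:ss", "y:ss"), inputs = function(data, ctx) {
        d <- need_xy(data); m <- means(ctx)
        c("x:ss" = sum((d$x - m[["mx"]])^2), "y:ss" = sum((d$y - m[["my"]])^2))
      }),
      list(vars = "xy:ss", inputs = function(data, ctx) {
        d <- need_xy(data); m <- means(ctx)
        c("xy:ss" = sum((d$x - m[["mx"]]) * (d$y - m[["my"]])))
      })
    ),
    finalizer = function(pooled, ctx) {
      n <- pooled[[1]][[".count"]]
      if (n < 2) abort_ss("securesum_stats_error", "pooled count must be >= 2")
      ssx <- pooled[[2]][["x:ss"]]; ssy <- pooled[[2]][["y:ss"]]
      if (ssx <= 0 || ssy <= 0)
        abort_ss("securesum_stats_error", "zero variance in x or y")
      list(r = pooled[[3]][["xy:ss"]] / sqrt(ssx * ssy), n = n)
    }
  )
}

#' Execute a cycle plan through the full protocol engine
#'
#' Runs each of the plan's cycles as one complete two-round
#' secure-summation study over the bus (never a computational shortcut),
#' making the pooled sums of earlier cycles available to the local-input
#' rules of later ones. Derived local inputs are rounded onto the ring's
#' fixed-point grid (10^-6 by default) before encoding.
#'
#' @param plan A [cycle_plan()].
#' @param party_data Named list: mailbox address -> that party's local
#'   dataset, in the representation the plan documents. At least 3 parties.
#' @param ring A [ring_config()].
#' @param rng Randomness source.
#' @param bus_factory Zero-argument function producing a fresh bus per
#'   cycle (default [memory_bus()]).
#' @return A `stat_result`: `method`, `statistics` (the finalizer's output),
#'   `pooled` (per-cycle named global sums — the only values ever
#'   reconstructed), `cycles_executed`, and `message_stats` per cycle.
#' @examples
#' data <- list("a@x" = c(1, 2), "b@x" = c(3, 4), "c@x" = c(5))
#' res <- run_plan(plan_mean(), data, rng = insecure_seeded_rng(1))
#' res$statistics$mean  # 3
#' @export
run_plan <- function(plan, party_data, ring = ring_config(),
                     rng = secure_rng(), bus_factory = memory_bus) {
  stopifnot(inherits(plan, "cycle_plan"))
  addrs <- names(party_data)
  if (is.null(addrs) || length(addrs) < 3L)
    abort_ss("securesum_stats_error",
             "party_data must be a named list of at least 3 parties")
  ctx <- list(pooled = list())
  message_stats <- list()
  executed <- 0L
  for (ci in seq_along(plan$cycles)) {
    cyc <- plan$cycles[[ci]]
    values <- lapply(party_data, function(d) {
      v <- cyc$inputs(d, ctx)
      if (!identical(names(v), cyc$vars))
        v <- stats::setNames(v[cyc$vars], cyc$vars)
      stats::setNames(fp_grid(as.numeric(v), ring), cyc$vars)
    })
    out <- tryCatch(
      run_secure_sum(values, study_name = sprintf("%s-cycle%d", plan$method, ci),
                     variable_names = cyc$vars, ring = ring,
                     bus = bus_factory(), rng = rng),
      securesum_error = function(e)
        abort_ss(class(e)[1], "cycle %d: %s", ci, conditionMessage(e))
    )
    executed <- executed + 1L
    ctx$pooled[[ci]] <- stats::setNames(out$result$sum, out$result$variable)
    message_stats[[ci]] <- out$bus_stats
  }
  structure(
    list(method = plan$method,
         statistics = plan$finalizer(ctx$pooled, ctx),
         pooled = ctx$pooled,
         cycles_executed = executed,
         message_stats = message_stats),
    class = "stat_result"
  )
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("<stat_result> %s after %d secure-sum cycle(s)\n",
              x$method, x$cycles_executed))
  stats <- x$statistics
  for (nm in names(stats)) {
    val <- stats[[nm]]
    if (is.numeric(val) && length(val) <= 6)
      cat(sprintf("  %s: %s\n", nm, paste(signif(val, 7), collapse = ", ")))
    else if (is.character(val) && length(val) == 1L)
      cat(sprintf("  %s: %s\n", nm, val))
  }
  invisible(x)
}
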