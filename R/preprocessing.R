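#' Remove gross outliers with the 3-sigma rule
#'
#' Keeps a measurement iff its dry yield lies within `mean +/- 3 * sd`,
#' with mean and sd computed once from the unfiltered data within the
#' measurement's scope. The default scope filters the test and control
#' groups separately, so a genuine treatment effect cannot push valid
#' measurements of the other group past the bounds. Under a normal
#' distribution the rule retains 99.7% of measurements.
#'
#' @param measurements a `yield_measurements` data frame.
#' @param scope `"group"` (default; per test/control group) or `"global"`
#'   (single pooled scope).
#' @return A list with `kept` (the retained measurements) and `report`
#'   (a `filter_report` data frame: one row per scope with `scope`,
#'   `n_input`, `n_removed`, `lower_bound`, `upper_bound` in kg/ha).
#' @examples
#' m <- simulate_measurements(example_layouts(1, 60, 120), sim_config(seed = 7))
#' f <- three_sigma_filter(m)
#' f$report
#' @export
three_sigma_filter <- function(measurements, scope = c("group", "global")) {
  scope <- match.arg(scope)
  df <- as.data.frame(measurements)
  key <- if (scope == "group") df$group else rep("all", nrow(df))
  keep <- logical(nrow(df))
  rows <- lapply(sort(unique(key)), function(k) {
    idx <- which(key == k)
    if (length(idx) < 2)
      stop(sprintf("scope '%s' has %d measurement(s); need at least 2 to estimate sd",
                   k, length(idx)), call. = FALSE)
    y <- df$dry_yield[idx]
    m <- mean(y); s <- sd(y)
    lo <- m - 3 * s; hi <- m + 3 * s   # s == 0 collapses bounds, keeps all
    inside <- y >= lo & y <= hi
    keep[idx] <<- inside
    data.frame(scope = k, n_input = length(idx), n_removed = sum(!inside),
               lower_bound = lo, upper_bound = hi, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  class(report) <- c("filter_report", "data.frame")
  kept <- df[keep, , drop = FALSE]
  rownames(kept) <- NULL
  class(kept) <- c("yield_measurements", "data.frame")
  list(kept = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("3-sigma filter report\n")
  for (i in seq_len(nrow(x)))
    cat(sprintf("  %-8s kept %d/%d (removed %d) within [%.1f, %.1f] kg/ha\n",
                x$scope[i], x$n_input[i] - x$n_removed[i], x$n_input[i],
                x$n_removed[i], x$lower_bound[i], x$upper_bound[i]))
  invisible(x)
}

# Proportional allocation with largest-remainder rounding.
# sizes: named stratum sizes; target: total to allocate.
# Ties broken by lexicographic stratum name; allocations capped at size.
largest_remainder <- function(sizes, target) {
  sizes <- sizes[order(names(sizes))]
  quota <- target * sizes / sum(sizes)
  alloc <- floor(quota)
  rem <- quota - alloc
  short <- target - sum(alloc)
  if (short > 0) {
    elig <- names(sizes)[alloc < sizes]
    ord <- elig[order(-rem[elig], elig)]
    bump <- head(ord, short)
    alloc[bump] <- alloc[bump] + 1
  }
  alloc
}

#' Balance test and control groups by stratified random sampling
#'
#' Each field is a stratum. Within each group, `target_per_group`
#' measurements are allocated across fields proportionally to field size
#' (largest-remainder rounding, lexicographic tie-break on `field_id`) and
#' drawn uniformly without replacement. Both groups end up with exactly
#' `target_per_group` measurements, so neither group dominates by acreage.
#'
#' @param measurements a `yield_measurements` data frame.
#' @param target_per_group measurements to keep per group; defaults to the
#'   size of the smaller group.
#' @param seed integer seed for the random draws.
#' @return A list with `sample` (the balanced measurements) and `plan`
#'   (a `sampling_plan` data frame: `group`, `field_id`, `stratum_size`,
#'   `allocated`; attributes `target_per_group` and `seed`).
#' @export
stratified_balance_sample <- function(measurements, target_per_group = NULL,
                                      seed = 1L) {
  df <- as.data.frame(measurements)
  sizes_by_group <- table(df$group)
  if (is.null(target_per_group))
    target_per_group <- min(sizes_by_group)
  if (any(sizes_by_group < target_per_group))
    stop(sprintf("target_per_group (%d) exceeds the size of group '%s' (%d)",
                 target_per_group,
                 names(sizes_by_group)[which.min(sizes_by_group)],
                 min(sizes_by_group)), call. = FALSE)
  set.seed(as.integer(seed))
  picked <- integer(0)
  plan <- list()
  for (g in sort(unique(df$group))) {
    idx_g <- which(df$group == g)
    sizes <- table(df$field_id[idx_g])
    sizes <- setNames(as.integer(sizes), names(sizes))
    alloc <- largest_remainder(sizes, target_per_group)
    for (f in names(alloc)) {
      idx_f <- idx_g[df$field_id[idx_g] == f]
      k <- alloc[[f]]
      if (k > 0) picked <- c(picked, sort(sample(idx_f, k)))
    }
    plan[[g]] <- data.frame(group = g, field_id = names(alloc),
                            stratum_size = as.integer(sizes[names(alloc)]),
                            allocated = as.integer(alloc),
                            stringsAsFactors = FALSE)
  }
  plan <- do.call(rbind, plan)
  rownames(plan) <- NULL
  class(plan) <- c("sampling_plan", "data.frame")
  attr(plan, "target_per_group") <- as.integer(target_per_group)
  attr(plan, "seed") <- as.integer(seed)
  out <- df[sort(picked), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("yield_measurements", "data.frame")
  list(sample = out, plan = plan)
}

#' @export
print.sampling_plan <- function(x, ...) {
  cat(sprintf("Stratified sampling plan: %d per group (seed %d)\n",
              attr(x, "target_per_group"), attr(x, "seed")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
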