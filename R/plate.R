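#' Subpopulation sets of proliferation constants
#'
#' A subpopulation set assigns each of `n` clonal subpopulations a per-day
#' proliferation constant \eqn{R_n} and an initial proportion; a well
#' seeded with \eqn{N_{n,0}} cells of subpopulation n contains
#' \eqn{N(t) = \sum_n N_{n,0} R_n^t} cells after t days.
#'
#' @param constants Positive per-day proliferation factors.
#' @param proportions Non-negative initial fractions summing to 1; defaults
#'   to equal proportions.
#' @param label Scenario tag (e.g. `"systematic"`, `"stochastic"`,
#'   `"instructive_t"`, `"permissive_t"`).
#' @return A list of class `subpop_set` with elements `constants`,
#'   `proportions` and `label`.
#' @export
subpop_set <- function(constants, proportions = NULL, label = "custom") {
  constants <- as.numeric(constants)
  if (!length(constants) || any(!is.finite(constants)) || any(constants <= 0)) {
    stop("constants must be positive and finite", call. = FALSE)
  }
  if (is.null(proportions)) {
    proportions <- rep(1 / length(constants), length(constants))
  }
  if (length(proportions) != length(constants) || any(proportions < 0) ||
      abs(sum(proportions) - 1) > 1e-9) {
    stop("proportions must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(constants = constants, proportions = proportions,
                 label = label),
            class = "subpop_set")
}

#' @export
print.subpop_set <- function(x, ...) {
  cat(sprintf("<subpop_set '%s': n = %d, R in [%.3f, %.3f], mean %.3f>\n",
              x$label, length(x$constants), min(x$constants),
              max(x$constants), mean(x$constants)))
  invisible(x)
}

#' Systematic (evenly spaced) proliferation constants
#'
#' `n` subpopulations with constants symmetrically spaced `spacing` apart
#' around `mean`: \eqn{R_i = mean + spacing (i - (n+1)/2)}, equal
#' proportions. Increasing `n` broadens the distribution while keeping the
#' mean fixed (n = 25 spans 1.4 to 2.6 at the defaults).
#'
#' @param n Number of subpopulations (≥ 1).
#' @param mean Mean per-day proliferation constant (default 2, one doubling
#'   per 24 h).
#' @param spacing Fixed spacing between adjacent constants (default 0.05).
#' @return A `subpop_set` labelled `"systematic"`.
#' @export
systematic_constants <- function(n, mean = 2, spacing = 0.05) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  i <- seq_len(n)
  subpop_set(mean + spacing * (i - (n + 1) / 2), label = "systematic")
}

#' Stochastic (normally sampled) proliferation constants
#'
#' `n` independent draws from a normal law centred on `mean`, truncated
#' below at `floor` (re-drawn), equal proportions. Deterministic given
#' `seed`.
#'
#' @inheritParams systematic_constants
#' @param sd Standard deviation of the normal law (> 0). The default 0.1 is
#'   a package choice; see the methods vignette.
#' @param floor Lower truncation bound for the constants (> 0).
#' @param seed Optional integer seed.
#' @return A `subpop_set` labelled `"stochastic"`.
#' @export
stochastic_constants <- function(n, mean = 2, sd = 0.1, floor = 0.05,
                                 seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (floor <= 0) stop("floor must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  r <- stats::rnorm(n, mean, sd)
  while (any(bad <- r < floor)) r[bad] <- stats::rnorm(sum(bad), mean, sd)
  subpop_set(r, label = "stochastic")
}

#' Instructive interface: uniform shift of all constants
#'
#' Models an interface that instructs every transmigrating cell alike: all
#' proliferation constants increase by `shift` (default 0.2, the reported
#' rise of the mean from 2.0 to 2.2), proportions unchanged, so the
#' population's heterogeneity (variance of constants) is preserved exactly.
#'
#' @param set A `subpop_set` (the non-transmigrated population).
#' @param shift Additive shift (default 0.2).
#' @return A `subpop_set` labelled `"instructive_t"`.
#' @export
instructive_transform <- function(set, shift = 0.2) {
  subpop_set(set$constants + shift, set$proportions, label = "instructive_t")
}

#' Permissive interface: selection of fast-proliferating subpopulations
#'
#' Models an interface that only lets inherently fast-proliferating cells
#' through: constants are sampled from the normal law conditioned on
#' \eqn{R \ge threshold} (rejection sampling), yielding a transmigrated
#' population enriched in high constants and less heterogeneous than the
#' parent.
#'
#' @inheritParams stochastic_constants
#' @param threshold Selection threshold (default 2.15).
#' @return A `subpop_set` labelled `"permissive_t"`.
#' @export
permissive_transform <- function(mean = 2, sd = 0.1, threshold = 2.15,
                                 n = 25, seed = NULL) {
  if (sd <= 0) stop("sd must be positive", call. = FALSE)
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  accept <- stats::pnorm(threshold, mean, sd, lower.tail = FALSE)
  if (accept < 1e-6) {
    stop("acceptance probability below 1e-6: threshold too extreme for sd",
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    cand <- stats::rnorm(ceiling((n - length(out)) / accept) + 10, mean, sd)
    out <- c(out, cand[cand >= threshold])
  }
  subpop_set(out[seq_len(n)], label = "permissive_t")
}

#' Limiting-dilution plate design
#'
#' The 96-well assay layout: blocks of `wells_per_block` wells seeded at
#' decreasing counts by serial random dilution. Source wells hold 1111
#' cells; each following block's well is seeded by randomly drawing from
#' the corresponding well of the previous block (1000, 100, 10, 1 cells).
#' The 1111-cell source block and the 1-cell block are excluded from the
#' coefficient-of-variation analysis by default (the latter because many
#' wells end up empty).
#'
#' @param wells_per_block Wells per dilution block (default 24).
#' @param seed_counts Strictly decreasing per-well seeding targets
#'   (default 1111, 1000, 100, 10, 1).
#' @param growth_days Incubation time in days (default 7).
#' @param pipette_cv Relative sd of multiplicative Gaussian noise applied to
#'   every transferred count (default 0; 0.03 models a 3% pipetting error).
#' @param analyzed_blocks Seed counts entering the CV profile
#'   (default 1000, 100, 10).
#' @return A list of class `plate_design`.
#' @export
plate_design <- function(wells_per_block = 24,
                         seed_counts = c(1111, 1000, 100, 10, 1),
                         growth_days = 7,
                         pipette_cv = 0,
                         analyzed_blocks = c(1000, 100, 10)) {
  if (wells_per_block < 2) stop("wells_per_block must be at least 2", call. = FALSE)
  if (is.unsorted(rev(seed_counts), strictly = TRUE)) {
    stop("seed_counts must be strictly decreasing", call. = FALSE)
  }
  if (pipette_cv < 0 || pipette_cv >= 1) {
    stop("pipette_cv must lie in [0, 1)", call. = FALSE)
  }
  if (!all(analyzed_blocks %in% seed_counts)) {
    stop("analyzed_blocks must be a subset of seed_counts", call. = FALSE)
  }
  structure(list(wells_per_block = wells_per_block,
                 seed_counts = seed_counts,
                 growth_days = growth_days,
                 pipette_cv = pipette_cv,
                 analyzed_blocks = analyzed_blocks),
            class = "plate_design")
}

# multivariate hypergeometric draw: k items without replacement from
# categories with the given counts (sequential conditional method)
rmvhyper <- function(k, counts) {
  total <- sum(counts)
  if (k > total) stop("cannot draw ", k, " from ", total, call. = FALSE)
  n <- length(counts)
  out <- integer(n)
  rem <- total
  for (i in seq_len(n - 1L)) {
    if (k == 0L) break
    out[i] <- stats::rhyper(1L, counts[i], rem - counts[i], k)
    k <- k - out[i]
    rem <- rem - counts[i]
  }
  out[n] <- k
  out
}

# apply pipette noise to a transfer target and cap at availability
transfer_count <- function(target, pipette_cv, cap) {
  k <- target
  if (pipette_cv > 0) {
    k <- max(0L, as.integer(round(target * (1 + stats::rnorm(1, 0, pipette_cv)))))
  }
  if (k > cap) {
    warning("transfer of ", k, " cells capped at parent availability (", cap,
            ")", call. = FALSE)
    k <- cap
  }
  as.integer(k)
}

#' Simulate one limiting-dilution plate
#'
#' Wells of the first block are seeded by a multinomial draw of the block's
#' target count with the set's subpopulation proportions (the infinite cell
#' pool). Each subsequent block's well is seeded by drawing its target
#' count without replacement (multivariate hypergeometric) from the seeded
#' composition of the corresponding well in the previous block. Optional
#' pipetting noise perturbs every transferred count multiplicatively before
#' rounding. Growth is deterministic exponential per subpopulation
#' ([grow()]), giving real-valued final totals per well. Fully
#' deterministic given `seed`.
#'
#' @param set A [subpop_set()].
#' @param design A [plate_design()].
#' @param seed Optional integer seed.
#' @return A list of class `simulated_plate` with `seeded` (one
#'   wells × subpopulations integer matrix per block), `final_totals` (one
#'   numeric vector per block), `design`, `label` and `rng_seed`.
#' @export
simulate_plate <- function(set, design = plate_design(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ns <- length(set$constants)
  wb <- design$wells_per_block
  sc <- design$seed_counts
  growth <- set$constants^design$growth_days
  seeded <- vector("list", length(sc))

  first <- matrix(0L, wb, ns)
  for (w in seq_len(wb)) {
    k <- transfer_count(sc[1L], design$pipette_cv, cap = Inf)
    first[w, ] <- as.integer(stats::rmultinom(1L, k, set$proportions))
  }
  seeded[[1L]] <- first
  for (b in seq_along(sc)[-1L]) {
    m <- matrix(0L, wb, ns)
    for (w in seq_len(wb)) {
      parent <- seeded[[b - 1L]][w, ]
      k <- transfer_count(sc[b], design$pipette_cv, cap = sum(parent))
      m[w, ] <- rmvhyper(k, parent)
    }
    seeded[[b]] <- m
  }
  names(seeded) <- as.character(sc)
  final_totals <- lapply(seeded, function(m) as.numeric(m %*% growth))
  structure(list(seeded = seeded, final_totals = final_totals,
                 design = design, label = set$label, rng_seed = seed),
            class = "simulated_plate")
}

#' Final well population from subpopulation growth
#'
#' Deterministic exponential growth: \eqn{N(t) = \sum_n N_{n,0} R_n^t}
#' with `t` in days; real-valued, no rounding.
#'
#' @param counts Non-negative seeded counts per subpopulation.
#' @param constants Matching per-day proliferation constants.
#' @param days Growth time in days (default 7).
#' @return Total cell number after `days` days.
#' @export
grow <- function(counts, constants, days = 7) {
  if (length(counts) != length(constants)) {
    stop("counts and constants must have the same length", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sum(counts * constants^days)
}

#' Coefficient-of-variation profile of a simulated plate
#'
#' For each analyzed block, the CV (sample sd / mean) of the final well
#' totals across the block's wells. Blocks with zero mean are reported as
#' `NA` with a warning.
#'
#' @param plate A [simulate_plate()] result.
#' @param analyzed_blocks Seed counts to analyze; defaults to the plate's
#'   design.
#' @return A data frame of class `cv_profile` with columns `seed_count`,
#'   `cv` and `n_wells`.
#' @export
cv_profile <- function(plate, analyzed_blocks = plate$design$analyzed_blocks) {
  rows <- lapply(analyzed_blocks, function(scount) {
    totals <- plate$final_totals[[as.character(scount)]]
    if (is.null(totals)) stop("block ", scount, " not present", call. = FALSE)
    m <- mean(totals)
    cv <- if (m == 0) {
      warning("block ", scount, " has zero mean final total; CV undefined",
              call. = FALSE)
      NA_real_
    } else {
      stats::sd(totals) / m
    }
    data.frame(seed_count = scount, cv = cv, n_wells = length(totals))
  })
  structure(do.call(rbind, rows), class = c("cv_profile", "data.frame"))
}

#' CV sweep over subpopulation counts and replicate plates
#'
#' Simulates replicate plates for every subpopulation count in `n_subpop`
#' under the systematic or stochastic model and collects the per-block CV
#' values in long format — the input to the nonparametric trend tests. In
#' the stochastic model each subpopulation count's constants are sampled
#' once and shared by all its replicate plates (the sampled population is
#' part of the scenario, as in the study); set
#' `resample_per_replicate = TRUE` to re-draw the constants for every
#' replicate instead.
#'
#' @param model `"systematic"` or `"stochastic"`.
#' @param n_subpop Vector of subpopulation counts (default 2:25).
#' @param replicates Replicate plates per subpopulation count (default 24).
#' @param design A [plate_design()].
#' @param mean,spacing,sd Model parameters (see [systematic_constants()]
#'   and [stochastic_constants()]).
#' @param resample_per_replicate Re-draw stochastic constants per replicate
#'   plate? Default `FALSE`.
#' @param seed Optional integer seed for the whole sweep.
#' @return A data frame with columns `model`, `n_subpop`, `replicate`,
#'   `seed_count`, `cv`.
#' @export
simulate_cv_sweep <- function(model = c("systematic", "stochastic"),
                              n_subpop = 2:25, replicates = 24,
                              design = plate_design(),
                              mean = 2, spacing = 0.05, sd = 0.1,
                              resample_per_replicate = FALSE,
                              seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", length(n_subpop) * replicates)
  i <- 0L
  for (n in n_subpop) {
    set_fixed <- if (model == "systematic") systematic_constants(n, mean, spacing)
                 else stochastic_constants(n, mean, sd)
    for (r in seq_len(replicates)) {
      set <- if (model == "stochastic" && resample_per_replicate) {
        stochastic_constants(n, mean, sd)
      } else set_fixed
      prof <- cv_profile(simulate_plate(set, design))
      i <- i + 1L
      out[[i]] <- data.frame(model = model, n_subpop = n, replicate = r,
                             seed_count = prof$seed_count, cv = prof$cv)
    }
  }
  do.call(rbind, out)
}

#' Replicate CV profiles for one scenario set
#'
#' Simulates `replicates` independent plates for a fixed subpopulation set
#' and returns the per-block CV values in long format, tagged with the
#' set's label.
#'
#' @param set A [subpop_set()].
#' @param design A [plate_design()].
#' @param replicates Number of replicate plates.
#' @param seed Optional integer seed.
#' @return A data frame with columns `label`, `replicate`, `seed_count`, `cv`.
#' @export
simulate_scenario_cv <- function(set, design = plate_design(),
                                 replicates = 24, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(replicates), function(r) {
    prof <- cv_profile(simulate_plate(set, design))
    data.frame(label = set$label, replicate = r,
               seed_count = prof$seed_count, cv = prof$cv)
  })
  do.call(rbind, out)
}

#' Interface scenario subpopulation sets
#'
#' Samples the four scenario populations compared at the matrix interface:
#' `instructive_nt` (normal law around `mean`), `instructive_t` (the same
#' constants uniformly shifted by `shift` — every cell responds alike),
#' `permissive_nt` (an independent normal sample) and `permissive_t`
#' (normal law conditioned on `R >= threshold` — only inherently fast
#' proliferators cross).
#'
#' @inheritParams stochastic_constants
#' @param shift Instructive shift (default 0.2).
#' @param threshold Permissive selection threshold (default 2.15).
#' @return A named list of four `subpop_set` objects.
#' @export
scenario_sets <- function(n = 25, mean = 2, sd = 0.1, shift = 0.2,
                          threshold = 2.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  instructive_nt <- stochastic_constants(n, mean, sd)
  instructive_nt$label <- "instructive_nt"
  instructive_t <- instructive_transform(instructive_nt, shift)
  permissive_nt <- stochastic_constants(n, mean, sd)
  permissive_nt$label <- "permissive_nt"
  permissive_t <- permissive_transform(mean, sd, threshold, n)
  list(instructive_nt = instructive_nt, instructive_t = instructive_t,
       permissive_nt = permissive_nt, permissive_t = permissive_t)
}

#' Nonparametric trend test on CV values
#'
#' Kruskal–Wallis test of the CV values across more than two groups, or a
#' Mann–Whitney (Wilcoxon rank-sum) test for exactly two groups. Groups
#' are the unique values of the `group` column in order of first
#' appearance; for two groups, `alternative` refers to the first group
#' relative to the second.
#'
#' @param cv_table Long data frame with a `cv` column and the grouping
#'   column.
#' @param group Name of the grouping column (e.g. `"seed_count"`,
#'   `"n_subpop"`, `"label"`).
#' @param alternative Alternative hypothesis for the two-group test.
#' @return A list of class `trend_test` with `method`, `statistic`,
#'   `p_value`, `group`, `n_groups` and `group_sizes`.
#' @export
compare_trends <- function(cv_table, group,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (!group %in% names(cv_table)) {
    stop("grouping column '", group, "' not found", call. = FALSE)
  }
  cv_table <- cv_table[is.finite(cv_table$cv), , drop = FALSE]
  g <- factor(cv_table[[group]], levels = unique(cv_table[[group]]))
  sizes <- table(g)
  if (nlevels(g) < 2L || any(sizes < 2L)) {
    stop("need at least two groups with at least two CV values each",
         call. = FALSE)
  }
  if (nlevels(g) > 2L) {
    ht <- stats::kruskal.test(cv_table$cv, g)
  } else {
    ht <- stats::wilcox.test(cv_table$cv[g == levels(g)[1L]],
                             cv_table$cv[g == levels(g)[2L]],
                             alternative = alternative, exact = FALSE)
  }
  structure(
    list(method = ht$method, statistic = unname(ht$statistic),
         p_value = ht$p.value, group = group, n_groups = nlevels(g),
         group_sizes = as.integer(sizes)),
    class = "trend_test"
  )
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("<trend_test (%s) on '%s': statistic = %.3f, p = %.3g>\n",
              x$method, x$group, x$statistic, x$p_value))
  invisible(x)
}
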