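#' Ground truth for a vector-autoregressive simulation
#'
#' Defines a stable VAR(p) process on a known sparse directed graph:
#' `x(t) = sum_l B[,,l] x(t-l) + e(t)` with white Gaussian innovations.
#' `B[i, j, l]` is the influence of region j on region i at lag l, so a
#' nonzero off-diagonal coefficient `B[k, j, l]` is a true directed edge
#' j -> k. Stability is checked through the spectral radius of the
#' companion matrix, which must be below 1.
#'
#' @param coefficients Numeric array `n x n x p` (a matrix is taken as
#'   `p = 1`).
#' @param noise_sd Innovation standard deviation.
#' @return An object of class `var_ground_truth` with fields `n_regions`,
#'   `coefficients`, `order`, `noise_sd`, `spectral_radius`, `true_edges`
#'   (data.frame from/to/lag/coef of nonzero off-diagonal coefficients).
#' @export
var_ground_truth <- function(coefficients, noise_sd = 1) {
  B <- coefficients
  if (is.matrix(B)) B <- array(B, c(nrow(B), ncol(B), 1L))
  if (length(dim(B)) != 3L || dim(B)[1L] != dim(B)[2L])
    stop("coefficients must be an n x n x p array")
  n <- dim(B)[1L]; p <- dim(B)[3L]
  comp <- matrix(0, n * p, n * p)
  for (l in seq_len(p)) comp[seq_len(n), (l - 1L) * n + seq_len(n)] <- B[, , l]
  if (p > 1L)
    comp[(n + 1L):(n * p), seq_len(n * (p - 1L))] <- diag(n * (p - 1L))
  rho <- max(Mod(eigen(comp, only.values = TRUE)$values))
  if (rho >= 1)
    stop(sprintf("unstable VAR: companion spectral radius %.4f >= 1", rho))
  idx <- which(B != 0, arr.ind = TRUE)
  off <- idx[idx[, 1L] != idx[, 2L], , drop = FALSE]
  true_edges <- data.frame(from = off[, 2L], to = off[, 1L], lag = off[, 3L],
                           coef = B[off])
  structure(list(n_regions = n, coefficients = B, order = p,
                 noise_sd = noise_sd, spectral_radius = rho,
                 true_edges = true_edges),
            class = "var_ground_truth")
}

#' @export
print.var_ground_truth <- function(x, ...) {
  cat(sprintf("<var_ground_truth> %d regions, order %d, %d directed edge(s), spectral radius %.3f\n",
              x$n_regions, x$order, nrow(x$true_edges), x$spectral_radius))
  invisible(x)
}

#' Build a sparse VAR ground truth from an edge list
#'
#' Convenience constructor: self-coupling `self_coef` at lag 1 on every
#' region (temporal smoothness of the regional signals) plus the listed
#' directed cross-couplings.
#'
#' @param n_regions Number of regions.
#' @param edges `data.frame` with columns `from`, `to`, `coef` and
#'   optionally `lag` (default 1); may be empty.
#' @param self_coef Lag-1 autoregressive coefficient of each region.
#' @param noise_sd Innovation SD.
#' @return A [var_ground_truth].
#' @export
var_from_edges <- function(n_regions, edges = NULL, self_coef = 0.3,
                           noise_sd = 1) {
  p <- if (!is.null(edges) && nrow(edges) && !is.null(edges$lag))
    max(1L, max(edges$lag)) else 1L
  B <- array(0, c(n_regions, n_regions, p))
  B[, , 1L][cbind(seq_len(n_regions), seq_len(n_regions))] <- self_coef
  if (!is.null(edges) && nrow(edges)) {
    lag <- if (is.null(edges$lag)) rep(1L, nrow(edges)) else edges$lag
    B[cbind(edges$to, edges$from, lag)] <- edges$coef
  }
  var_ground_truth(B, noise_sd = noise_sd)
}

#' Simulate a VAR realization
#'
#' Draws a seeded Gaussian-innovation realization of the ground-truth
#' process, discarding an initial burn-in so the retained samples are from
#' the stationary regime.
#'
#' @param gt A [var_ground_truth].
#' @param T Number of retained time points (200+ matches typical resting
#'   fMRI runs).
#' @param seed Integer seed (caller's RNG state restored).
#' @param burn_in Initial samples discarded.
#' @param subject_id Identifier stored in the output.
#' @return A [region_ts] of dimension `n_regions x T`.
#' @export
simulate_var <- function(gt, T = 207L, seed = 1L, burn_in = 500L,
                         subject_id = "sim") {
  stopifnot(inherits(gt, "var_ground_truth"))
  n <- gt$n_regions; p <- gt$order
  total <- T + burn_in
  x <- with_seed(seed, {
    e <- matrix(stats::rnorm(n * total, sd = gt$noise_sd), n, total)
    x <- matrix(0, n, total)
    x[, seq_len(p)] <- e[, seq_len(p)]
    for (t in (p + 1L):total) {
      acc <- e[, t]
      for (l in seq_len(p)) acc <- acc + gt$coefficients[, , l] %*% x[, t - l]
      x[, t] <- acc
    }
    x
  })
  region_ts(x[, (burn_in + 1L):total, drop = FALSE],
            subject_id = subject_id)
}

#' Group-effect specification for synthetic cohorts
#'
#' Describes how the patient group's coupling differs from the control
#' group's. `"flip"` plants the j -> k coupling in patients and the reversed
#' k -> j coupling (same magnitude) in controls, so undirected connectivity
#' strength is matched between groups and only the direction differs.
#' `"scale"` gives patients coefficient `coef` and controls `control_coef`.
#' `"none"` yields a null cohort (identical processes).
#'
#' @param type `"flip"`, `"scale"` or `"none"`.
#' @param from,to Source and target region indices of the planted coupling.
#' @param lag Lag of the planted coupling.
#' @param coef Patient-group coefficient.
#' @param control_coef Control-group coefficient for `"scale"` (default 0).
#' @return A list of class `cohort_effect`.
#' @export
cohort_effect <- function(type = c("flip", "scale", "none"), from = 1L,
                          to = 2L, lag = 1L, coef = 0.8, control_coef = 0) {
  type <- match.arg(type)
  structure(list(type = type, from = as.integer(from), to = as.integer(to),
                 lag = as.integer(lag), coef = coef,
                 control_coef = control_coef),
            class = "cohort_effect")
}

jittered_gt <- function(gt, jitter_sd) {
  B <- gt$coefficients
  nz <- B != 0
  B[nz] <- B[nz] * (1 + stats::rnorm(sum(nz), sd = jitter_sd))
  g <- tryCatch(var_ground_truth(B, gt$noise_sd), error = function(e) NULL)
  if (is.null(g)) {
    # rare unstable draw: shrink toward the base process
    g <- var_ground_truth(0.9 * B, gt$noise_sd)
  }
  g
}

#' Generate a two-group synthetic cohort with known directed ground truth
#'
#' Simulates per-subject regional time series from group-specific VAR
#' processes (see [cohort_effect]) with subject-level multiplicative jitter
#' on the nonzero coefficients, plus a covariate table (age, sex and six
#' motion summary scalars) with a configurable group-age confound. Defaults
#' mirror the unbalanced clinical design this machinery targets: 15
#' controls vs 95 patients, 207 retained time points.
#'
#' @param n_control,n_patient Group sizes.
#' @param n_regions Number of regions.
#' @param T Time points per subject.
#' @param effect A [cohort_effect].
#' @param self_coef Baseline lag-1 self-coupling of every region.
#' @param noise_sd Innovation SD.
#' @param jitter_sd SD of the multiplicative subject-level coefficient
#'   jitter.
#' @param age_confound Mean age difference added to the control group
#'   (years); default 4, echoing typical case-control imbalance.
#' @param seed Integer seed.
#' @return List with `series` (list of [region_ts]), `subjects`
#'   (data.frame: subject_id, group, age, sex, m1..m6) and `truth`
#'   (control/patient ground truths and the effect).
#' @export
make_group_cohort <- function(n_control = 15L, n_patient = 95L,
                              n_regions = 10L, T = 207L,
                              effect = cohort_effect(), self_coef = 0.3,
                              noise_sd = 1, jitter_sd = 0.1,
                              age_confound = 4, seed = 1L) {
  ctrl_edges <- pat_edges <- NULL
  if (effect$type == "flip") {
    pat_edges <- data.frame(from = effect$from, to = effect$to,
                            coef = effect$coef, lag = effect$lag)
    ctrl_edges <- data.frame(from = effect$to, to = effect$from,
                             coef = effect$coef, lag = effect$lag)
  } else if (effect$type == "scale") {
    pat_edges <- data.frame(from = effect$from, to = effect$to,
                            coef = effect$coef, lag = effect$lag)
    if (effect$control_coef != 0)
      ctrl_edges <- data.frame(from = effect$from, to = effect$to,
                               coef = effect$control_coef, lag = effect$lag)
  }
  gt_ctrl <- var_from_edges(n_regions, ctrl_edges, self_coef, noise_sd)
  gt_pat <- var_from_edges(n_regions, pat_edges, self_coef, noise_sd)
  n_total <- n_control + n_patient
  group <- factor(rep(c("CTR", "PAT"), c(n_control, n_patient)),
                  levels = c("CTR", "PAT"))
  with_seed(seed, {
    age <- stats::rnorm(n_total, mean = 68, sd = 10) +
      ifelse(group == "CTR", age_confound, 0)
    sex <- stats::rbinom(n_total, 1L, 0.7)
    motion <- matrix(abs(stats::rnorm(n_total * 6L, sd = 0.2)), n_total, 6L,
                     dimnames = list(NULL, paste0("m", 1:6)))
    subj_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    series <- vector("list", n_total)
    for (s in seq_len(n_total)) {
      base <- if (group[s] == "CTR") gt_ctrl else gt_pat
      gt_s <- if (jitter_sd > 0) jittered_gt(base, jitter_sd) else base
      series[[s]] <- simulate_var(gt_s, T = T, seed = subj_seeds[s],
                                  subject_id = sprintf("S%03d", s))
    }
    subjects <- data.frame(subject_id = sprintf("S%03d", seq_len(n_total)),
                           group = group, age = age, sex = sex, motion,
                           stringsAsFactors = FALSE)
    list(series = series, subjects = subjects,
         truth = list(control = gt_ctrl, patient = gt_pat, effect = effect,
                      jitter_sd = jitter_sd, seed = seed))
  })
}

#' Canonical small directed test networks
#'
#' Named binary fixtures used throughout the test suite, each bundled with
#' hand- or enumeration-derived reference values.
#'
#' @return Named list; each element has `adjacency` and `oracle` (a list of
#'   known measure values).
#' @export
fixture_networks <- function() {
  cyc3 <- matrix(c(0, 1, 0,
                   0, 0, 1,
                   1, 0, 0), 3, 3, byrow = TRUE)
  dag3 <- matrix(c(0, 1, 1,
                   0, 0, 1,
                   0, 0, 0), 3, 3, byrow = TRUE)
  bidir3 <- matrix(c(0, 1, 1,
                     1, 0, 1,
                     1, 1, 0), 3, 3, byrow = TRUE)
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1; star[2:5, 1] <- 1
  two_cliques <- matrix(0, 6, 6)
  two_cliques[1:3, 1:3] <- bidir3
  two_cliques[4:6, 4:6] <- bidir3
  rnd10 <- with_seed(42L, {
    a <- matrix(as.numeric(stats::runif(100) < 0.3), 10, 10)
    diag(a) <- 0
    a
  })
  list(
    cycle3 = list(adjacency = cyc3,
                  oracle = list(diameter = 2, E = 0.75, clustering = c(1, 1, 1),
                                transitivity = 0.5)),
    dag_triangle = list(adjacency = dag3,
                        oracle = list(clustering = c(0, 0, 0), transitivity = 0)),
    bidir_triangle = list(adjacency = bidir3,
                          oracle = list(clustering = c(1, 1, 1), E = 1)),
    complete4 = list(adjacency = k4,
                     oracle = list(E = 1, LE = 1, diameter = 1)),
    star5 = list(adjacency = star,
                 oracle = list(le_center = 0)),
    two_cliques = list(adjacency = two_cliques,
                       oracle = list(Q = 0.5,
                                     membership = c(1, 1, 1, 2, 2, 2))),
    random10 = list(adjacency = rnd10, oracle = list())
  )
}
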