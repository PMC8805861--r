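trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Default density grid
#'
#' The analysis density range: 1% to 50% of possible directed edges in steps
#' of 1%. 50% is the maximum attainable density of an antisymmetric matrix.
#'
#' @return Numeric vector `seq(0.01, 0.50, by = 0.01)`.
#' @export
default_densities <- function() seq(0.01, 0.50, by = 0.01)

measure_groups <- c("degree", "efficiency", "local_efficiency", "clustering",
                    "transitivity", "modularity", "diameter")

compute_measures_one <- function(net, measures, louvain_restarts, seed) {
  labels <- rownames(net$adjacency)
  if (is.null(labels)) labels <- paste0("R", seq_len(nrow(net$adjacency)))
  nodal <- list(); global <- list()
  if ("degree" %in% measures) {
    dg <- degrees(net)
    nodal$in_degree <- dg$in_degree
    nodal$out_degree <- dg$out_degree
    nodal$degree <- dg$degree
  }
  need_dist <- any(c("efficiency", "diameter") %in% measures)
  dist <- if (need_dist) directed_distances(net)
  if ("efficiency" %in% measures) {
    ge <- global_efficiency(net, dist)
    nodal$in_global_eff <- ge$e_in
    nodal$out_global_eff <- ge$e_out
    nodal$global_eff <- (ge$e_in + ge$e_out) / 2
    global$E_in <- ge$E_in; global$E_out <- ge$E_out; global$E <- ge$E
  }
  if ("local_efficiency" %in% measures) {
    le <- local_efficiency(net)
    nodal$in_local_eff <- le$le_in
    nodal$out_local_eff <- le$le_out
    nodal$local_eff <- (le$le_in + le$le_out) / 2
    global$LE_in <- le$LE_in; global$LE_out <- le$LE_out; global$LE <- le$LE
  }
  if ("clustering" %in% measures) {
    cl <- directed_clustering(net)
    nodal$clustering <- cl
    global$clustering_mean <- mean(cl)
  }
  if ("transitivity" %in% measures)
    global$transitivity <- transitivity_directed(net)
  if ("modularity" %in% measures)
    global$modularity <- if (sum(net$adjacency) > 0)
      modularity_louvain(net, n_restarts = louvain_restarts, seed = seed)$Q else NA_real_
  if ("diameter" %in% measures)
    global$diameter <- dist$diameter
  n <- length(labels)
  data.frame(
    measure = c(rep(names(nodal), each = n), names(global)),
    region = c(rep(labels, times = length(nodal)),
               rep("GLOBAL", length(global))),
    density = net$density,
    value = c(unlist(nodal, use.names = FALSE),
              unlist(global, use.names = FALSE)),
    stringsAsFactors = FALSE)
}

#' Graph measures across a density range
#'
#' Thresholds a connectivity matrix at every density of the grid and
#' computes the selected nodal and global measures, yielding one long-format
#' table (`measure`, `region` — a label or `"GLOBAL"` —, `density`,
#' `value`). Densities whose edge count exceeds the number of positive
#' weights are skipped with a warning.
#'
#' @param mat A clipped [conn_matrix].
#' @param densities Density grid, default [default_densities()].
#' @param mode `"binary"` or `"weighted"` thresholding.
#' @param measures Character subset of
#'   `c("degree", "efficiency", "local_efficiency", "clustering",
#'   "transitivity", "modularity", "diameter")`, or `"all"`.
#' @param louvain_restarts Restarts for the modularity optimization.
#' @param seed Seed for the modularity restarts.
#' @return A long-format `data.frame` of class `measure_curves`.
#' @export
measures_over_densities <- function(mat, densities = default_densities(),
                                    mode = c("binary", "weighted"),
                                    measures = "all",
                                    louvain_restarts = 100L, seed = 1L) {
  mode <- match.arg(mode)
  if (!length(densities) || any(diff(densities) <= 0) || any(densities <= 0))
    stop("densities must be a strictly increasing positive grid")
  if (identical(measures, "all")) measures <- measure_groups
  measures <- match.arg(measures, measure_groups, several.ok = TRUE)
  rows <- vector("list", length(densities))
  for (i in seq_along(densities)) {
    net <- tryCatch(threshold_by_density(mat, densities[i], mode = mode),
                    error = function(e) e)
    if (inherits(net, "error")) {
      warning(sprintf("density %.2f skipped: %s", densities[i],
                      conditionMessage(net)))
      next
    }
    rows[[i]] <- compute_measures_one(net, measures, louvain_restarts, seed)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("measure_curves", class(out))
  out
}

#' Area under the measure-density curve
#'
#' Integrates each measure curve over the density grid by the trapezoidal
#' rule, collapsing the density dimension to a single threshold-robust value
#' per measure and region (or per global measure).
#'
#' @param curves A `measure_curves` long table (from
#'   [measures_over_densities]).
#' @return A `data.frame` with columns `measure`, `region`, `auc` and
#'   attributes `density_range`.
#' @export
auc_over_densities <- function(curves) {
  curves <- as.data.frame(curves)
  need <- c("measure", "region", "density", "value")
  if (!all(need %in% names(curves)))
    stop("curves must have columns measure, region, density, value")
  key <- interaction(curves$measure, curves$region, drop = TRUE)
  parts <- split(curves, key)
  out <- do.call(rbind, lapply(parts, function(d) {
    d <- d[order(d$density), , drop = FALSE]
    if (nrow(d) < 2L)
      stop("AUC needs at least 2 densities per curve")
    if (any(diff(d$density) <= 0))
      stop("density grid must be strictly increasing")
    v <- d$value
    v[!is.finite(v)] <- NA
    if (anyNA(v)) {
      ok <- !is.na(v)
      if (sum(ok) < 2L) return(data.frame(measure = d$measure[1L],
                                          region = d$region[1L], auc = NA_real_))
      d <- d[ok, ]; v <- v[ok]
    }
    data.frame(measure = d$measure[1L], region = d$region[1L],
               auc = trapz(d$density, v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "density_range") <- range(curves$density)
  out
}
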