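#' Pointwise two-sample t map between trial-pooled CDV moduli
#'
#' Student's t contrast at every (axis point, grid point): the two samples
#' are the CDV moduli pooled across all trials of each run at the same
#' latency (time domain) or frequency bin (frequency domain). The default
#' statistic is the pooled-variance two-sample t with a two-sided p value;
#' Welch's unequal-variance form is available via `var_equal = FALSE`.
#' Cells where both samples have zero variance are flagged degenerate with
#' `t = NA, p = 1`.
#'
#' @param dataset_a,dataset_b numeric arrays `trials x axis points x grid
#'   points` of moduli (see [cdv_moduli()]); at least 2 trials each.
#' @param axis axis-point values (ms or Hz).
#' @param domain `"time"` or `"frequency"`.
#' @param label contrast label, e.g. `"Motor1 vs Supra2"`.
#' @param var_equal pooled-variance t (TRUE, default) or Welch.
#' @return An object of class `spm_map`: `t`, `p`, `degenerate` arrays
#'   (`axis x points`), plus `axis`, `domain`, `label`, trial counts.
#' @export
pointwise_t_map <- function(dataset_a, dataset_b, axis,
                            domain = c("time", "frequency"),
                            label = "A vs B", var_equal = TRUE) {
  domain <- match.arg(domain)
  da <- dim(dataset_a); db <- dim(dataset_b)
  if (length(da) != 3L || length(db) != 3L || any(da[2:3] != db[2:3]))
    stop("datasets must be trials x axis x points arrays on the same lattice")
  if (da[1] < 2L || db[1] < 2L) stop("each side needs at least 2 trials")
  if (length(axis) != da[2]) stop("'axis' must match the axis dimension")
  n1 <- da[1]; n2 <- db[1]
  m1 <- colMeans(dataset_a); m2 <- colMeans(dataset_b)          # axis x points
  v1 <- colMeans(sweep(dataset_a, c(2, 3), m1)^2) * n1 / (n1 - 1)
  v2 <- colMeans(sweep(dataset_b, c(2, 3), m2)^2) * n2 / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- array(n1 + n2 - 2, dim = dim(se))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  degen <- se == 0
  tval <- (m1 - m2) / se
  tval[degen] <- NA_real_
  p <- 2 * stats::pt(-abs(tval), df)
  p[degen] <- 1
  structure(list(t = tval, p = p, degenerate = degen, axis = as.numeric(axis),
                 domain = domain, label = label, n = c(n1, n2)),
            class = "spm_map")
}

#' @export
print.spm_map <- function(x, ...) {
  cat(sprintf("<spm_map> %s [%s]: %d axis x %d grid points, min p = %.3g\n",
              x$label, x$domain, nrow(x$p), ncol(x$p), min(x$p)))
  invisible(x)
}

bind_trials <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1] + db[1], da[2], da[3]))
  out[seq_len(da[1]), , ] <- a
  out[da[1] + seq_len(db[1]), , ] <- b
  out
}

#' Fully combinatorial run contrasts
#'
#' Without merging, every run of side A is contrasted against every run of
#' side B, giving `|A| x |B|` SPM maps (2 Motor runs vs 2 Supra runs give a
#' set of four). With `merge` supplied, the B runs and the merge runs are
#' first combined trial-wise in all `|B| x |merge|` pairings and each merged
#' dataset is contrasted against each A run (2 Motor vs merged 2 Supra +
#' 2 Sub give a set of eight).
#'
#' @param runs_a,runs_b named lists of `trials x axis x points` moduli
#'   arrays.
#' @param axis axis values shared by all runs.
#' @param merge optional named list of runs of a second baseline condition
#'   to merge combinatorially with `runs_b`.
#' @param domain `"time"` or `"frequency"`.
#' @param var_equal see [pointwise_t_map()].
#' @return list of [pointwise_t_map()] results, labelled `A vs B`.
#' @export
combinatorial_contrasts <- function(runs_a, runs_b, axis, merge = NULL,
                                    domain = c("time", "frequency"),
                                    var_equal = TRUE) {
  domain <- match.arg(domain)
  if (!length(runs_a) || !length(runs_b)) stop("empty run list")
  name_or <- function(lst, stem)
    if (is.null(names(lst))) paste0(stem, seq_along(lst)) else names(lst)
  na <- name_or(runs_a, "A"); nb <- name_or(runs_b, "B")
  if (!is.null(merge)) {
    if (!length(merge)) stop("empty run list in 'merge'")
    nm <- name_or(merge, "C")
    merged <- list()
    for (i in seq_along(runs_b)) for (j in seq_along(merge))
      merged[[paste0(nb[i], "+", nm[j])]] <- bind_trials(runs_b[[i]], merge[[j]])
    runs_b <- merged
    nb <- names(merged)
  }
  maps <- list()
  for (i in seq_along(runs_a)) for (j in seq_along(runs_b)) {
    lab <- paste(na[i], "vs", nb[j])
    maps[[lab]] <- pointwise_t_map(runs_a[[i]], runs_b[[j]], axis,
                                   domain = domain, label = lab,
                                   var_equal = var_equal)
  }
  maps
}

#' All-maps intersection activation map
#'
#' A point is active in the combined map iff it shows a significant change
#' (`p < alpha`) in *every* SPM map of the set. `alpha` is interpreted as
#' the already-corrected pointwise threshold (default 1e-4); to apply a
#' Bonferroni family correction instead, pass `family_size` and the
#' uncorrected level is `alpha / family_size`.
#'
#' @param maps list of [pointwise_t_map()] results sharing domain and axis.
#' @param alpha significance threshold applied pointwise to each map.
#' @param family_size optional Bonferroni family size dividing `alpha`.
#' @return An object of class `activation_map`: logical `active` matrix
#'   (`axis x points`), `axis`, `domain`, `alpha` used and set size `m`.
#' @export
intersect_activation <- function(maps, alpha = 1e-4, family_size = NULL) {
  if (!length(maps)) stop("need at least one SPM map")
  domains <- unique(vapply(maps, `[[`, character(1), "domain"))
  if (length(domains) != 1L) stop("cannot intersect maps from mixed domains")
  ax <- maps[[1]]$axis
  for (m in maps) if (!isTRUE(all.equal(m$axis, ax))) stop("maps must share the axis")
  if (!is.null(family_size)) alpha <- alpha / family_size
  active <- Reduce(`&`, lapply(maps, function(m) m$p < alpha))
  structure(list(active = active, axis = ax, domain = domains,
                 alpha = alpha, m = length(maps)),
            class = "activation_map")
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("<activation_map> [%s] intersection of %d maps at alpha = %g: %d active cell(s)\n",
              x$domain, x$m, x$alpha, sum(x$active)))
  invisible(x)
}

#' Spatially contiguous clusters of an activation map
#'
#' Collapses the activation map over its axis (a grid point counts as
#' active if it is active at any axis point) and groups active grid points
#' into 6-connected components on the source grid.
#'
#' @param amap an [intersect_activation()] result.
#' @param grid the [source_grid()] the maps were computed on.
#' @return data frame with one row per cluster: `cluster`, `n_points`,
#'   center-of-mass coordinates (mm) and the axis range over which the
#'   cluster is active; zero rows when nothing is active.
#' @export
activation_clusters <- function(amap, grid) {
  stopifnot(inherits(amap, "activation_map"), inherits(grid, "source_grid"))
  pt_active <- which(apply(amap$active, 2, any))
  empty <- data.frame(cluster = integer(), n_points = integer(),
                      x = numeric(), y = numeric(), z = numeric(),
                      axis_min = numeric(), axis_max = numeric())
  if (!length(pt_active)) return(empty)
  shp <- grid$shape
  idx3 <- arrayInd(pt_active, shp)
  key <- function(ijk) (ijk[, 3] - 1) * shp[1] * shp[2] + (ijk[, 2] - 1) * shp[1] + ijk[, 1]
  in_set <- new.env(hash = TRUE)
  for (r in seq_len(nrow(idx3))) assign(as.character(key(idx3[r, , drop = FALSE])), r, envir = in_set)
  labels <- integer(nrow(idx3))
  cl <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (r in seq_len(nrow(idx3))) {
    if (labels[r]) next
    cl <- cl + 1L
    queue <- r
    labels[r] <- cl
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      for (o in seq_len(6)) {
        nb <- idx3[cur, ] + offs[o, ]
        if (any(nb < 1) || any(nb > shp)) next
        hit <- mget(as.character(key(rbind(nb))), envir = in_set, ifnotfound = list(NULL))[[1]]
        if (!is.null(hit) && !labels[hit]) {
          labels[hit] <- cl
          queue <- c(queue, hit)
        }
      }
    }
  }
  coords <- grid_coords(grid)[pt_active, , drop = FALSE]
  do.call(rbind, lapply(seq_len(cl), function(c) {
    sel <- labels == c
    ax_on <- amap$axis[apply(amap$active[, pt_active[sel], drop = FALSE], 1, any)]
    data.frame(cluster = c, n_points = sum(sel),
               x = mean(coords[sel, 1]), y = mean(coords[sel, 2]), z = mean(coords[sel, 3]),
               axis_min = min(ax_on), axis_max = max(ax_on))
  }))
}
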