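#' Extract directed, latency-stamped links from an MI map
#'
#' Reads the interregional links off a normalized (or threshold-averaged)
#' MI map: cells with `value >= mi_threshold` whose delay magnitude falls
#' in the conduction band (default `5 <= |tau| <= 20` ms, excluding
#' near-zero lags that reflect common drive and long lags beyond a few
#' synapses) and whose latency lies in the analysis range (default -50 to
#' 100 ms) are clustered into 4-connected components on the `(t, tau)`
#' lattice. Each component becomes one link:
#' the sign of tau gives the direction (positive: ROI1 leads ROI2), the
#' source onset is the earliest latency of the leading region's windows,
#' the target activation window spans the lagged windows of the following
#' region, and the strength is the component's MI maximum. The link delay
#' is the component's *dominant* delay: the tau row holding the largest
#' summed MI mass within the component. (A genuine lagged coupling forms a
#' ridge at its lag persisting across the whole activation; transient
#' near-ceiling cells at other delays can carry the single largest cell
#' without representing the linkage, so the peak cell's tau is not used.)
#'
#' @param map a normalized [mi_map()] or an [average_mi_maps()] result.
#' @param mi_threshold linkage threshold on the normalized MI.
#' @param delay_band `c(min, max)` admissible `|tau|` in ms.
#' @param t_range analysed latency range, ms.
#' @return data frame of class `influence_links` with one row per link:
#'   `source`, `target`, `source_onset_ms`, `target_on_ms`,
#'   `target_off_ms`, `delay_ms`, `strength`, `n_cells`. Zero rows when no
#'   component survives.
#' @export
extract_links <- function(map, mi_threshold = 0.4, delay_band = c(5, 20),
                          t_range = c(-50, 100)) {
  stopifnot(inherits(map, "mi_map"))
  if (!isTRUE(map$normalized) && !inherits(map, "avg_mi_map"))
    stop("extract_links expects a normalized MI map")
  v <- map$values
  tau <- map$tau
  tt <- map$t
  mask <- !is.na(v) & v >= mi_threshold &
    outer(rep(TRUE, length(tt)), abs(tau) >= delay_band[1] & abs(tau) <= delay_band[2]) &
    outer(tt >= t_range[1] & tt <= t_range[2], rep(TRUE, length(tau)))

  empty <- structure(
    data.frame(source = character(), target = character(),
               source_onset_ms = numeric(), target_on_ms = numeric(),
               target_off_ms = numeric(), delay_ms = numeric(),
               strength = numeric(), n_cells = integer()),
    class = c("influence_links", "data.frame"))
  if (!any(mask)) return(empty)

  comp <- label_components(mask)
  rows <- lapply(seq_len(max(comp, na.rm = TRUE)), function(k) {
    cells <- which(comp == k, arr.ind = TRUE)
    vals <- v[cells]
    mass <- tapply(vals, cells[, 2], sum)
    tau_pk <- tau[as.integer(names(mass))[which.max(mass)]]
    t_cells <- tt[cells[, 1]]
    lag_cells <- tt[cells[, 1]] + tau[cells[, 2]]
    if (tau_pk > 0) {
      data.frame(source = map$pair[1], target = map$pair[2],
                 source_onset_ms = min(t_cells),
                 target_on_ms = min(lag_cells), target_off_ms = max(lag_cells),
                 delay_ms = tau_pk, strength = max(vals),
                 n_cells = nrow(cells))
    } else {
      data.frame(source = map$pair[2], target = map$pair[1],
                 source_onset_ms = min(lag_cells),
                 target_on_ms = min(t_cells), target_off_ms = max(t_cells),
                 delay_ms = -tau_pk, strength = max(vals),
                 n_cells = nrow(cells))
    }
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$source_onset_ms), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("influence_links", "data.frame")
  out
}

# 4-connected component labelling of a logical matrix (flood fill).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- matrix(NA_integer_, d[1], d[2])
  cur <- 0L
  for (start in which(mask)) {
    if (!is.na(lab[start])) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      s <- queue[[1]]; queue <- queue[-1]
      i <- (s - 1L) %% d[1] + 1L
      j <- (s - 1L) %/% d[1] + 1L
      for (nb in list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))) {
        if (nb[1] < 1L || nb[1] > d[1] || nb[2] < 1L || nb[2] > d[2]) next
        s2 <- (nb[2] - 1L) * d[1] + nb[1]
        if (mask[s2] && is.na(lab[s2])) {
          lab[s2] <- cur
          queue <- c(queue, s2)
        }
      }
    }
  }
  lab
}

#' Assemble an influence diagram from per-pair link sets
#'
#' An influence diagram arranges the ROIs in successive rows with time
#' flowing left to right; each link is an arrow whose base marks the onset
#' latency of the leading activation and whose head points at the full
#' activation window of the following region.
#'
#' @param links an `influence_links` data frame (or a list of them, e.g.
#'   one per ROI pair; they are row-bound).
#' @param roi_order character vector fixing the row order; every link
#'   endpoint must appear in it.
#' @param analysis_window `c(lo, hi)` ms covered by the analysis.
#' @param threshold the MI threshold the links were extracted at.
#' @return An object of class `influence_diagram`.
#' @export
build_influence_diagram <- function(links, roi_order,
                                    analysis_window = c(-50, 100),
                                    threshold = 0.4) {
  if (is.list(links) && !is.data.frame(links))
    links <- do.call(rbind, links)
  if (is.null(links) || !nrow(links)) {
    links <- data.frame(source = character(), target = character(),
                        source_onset_ms = numeric(), target_on_ms = numeric(),
                        target_off_ms = numeric(), delay_ms = numeric(),
                        strength = numeric(), n_cells = integer())
  }
  bad <- setdiff(unique(c(links$source, links$target)), roi_order)
  if (length(bad)) stop("links reference unknown ROIs: ", paste(bad, collapse = ", "))
  links <- links[order(links$source_onset_ms), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(rois = roi_order, links = links,
                 analysis_window = analysis_window, threshold = threshold),
            class = "influence_diagram")
}

#' @export
print.influence_diagram <- function(x, ...) {
  cat(sprintf("<influence_diagram> %d ROIs, %d link(s), window %g..%g ms, c = %g\n",
              length(x$rois), nrow(x$links),
              x$analysis_window[1], x$analysis_window[2], x$threshold))
  if (nrow(x$links)) {
    with(x$links, cat(sprintf("  %s @%g ms -> %s [%g, %g] ms (delay %g ms, MI %.2f)\n",
                              source, source_onset_ms, target,
                              target_on_ms, target_off_ms, delay_ms, strength)))
  } else cat("  no links extracted\n")
  invisible(x)
}

#' Plot an influence diagram
#'
#' ROIs on rows, time on the x axis; arrows run from the source onset to
#' the target's activation window (drawn as a box).
#'
#' @param x an [build_influence_diagram()] result.
#' @param ... unused.
#' @export
plot.influence_diagram <- function(x, ...) {
  n <- length(x$rois)
  ypos <- stats::setNames(rev(seq_len(n)), x$rois)
  graphics::plot(NA, xlim = x$analysis_window, ylim = c(0.5, n + 0.5),
                 yaxt = "n", xlab = "time (ms)", ylab = "",
                 main = sprintf("influence diagram (c = %g)", x$threshold))
  graphics::axis(2, at = ypos, labels = names(ypos), las = 1)
  graphics::abline(h = ypos, col = "grey85")
  if (nrow(x$links)) for (i in seq_len(nrow(x$links))) {
    l <- x$links[i, ]
    graphics::rect(l$target_on_ms, ypos[l$target] - 0.15,
                   l$target_off_ms, ypos[l$target] + 0.15,
                   border = "firebrick", lwd = 1.2)
    graphics::arrows(l$source_onset_ms, ypos[l$source],
                     l$target_on_ms, ypos[l$target],
                     length = 0.08, col = "firebrick")
  }
  invisible(x)
}

#' Serialize an influence diagram (or links) to JSON
#'
#' @param x an `influence_diagram` or `influence_links` object.
#' @param path optional file path; when NULL the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
diagram_to_json <- function(x, path = NULL) {
  payload <- if (inherits(x, "influence_diagram"))
    list(rois = x$rois, analysis_window = x$analysis_window,
         threshold = x$threshold, links = x$links)
  else list(links = as.data.frame(x))
  js <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
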