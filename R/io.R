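#' Write / read a ROI catalog as JSON
#'
#' @param rois list of [roi_spec()] objects.
#' @param path JSON file path.
#' @export
write_roi_catalog <- function(rois, path) {
  payload <- lapply(rois, function(r)
    list(label = r$label, center = r$center, radius = r$radius,
         principal_direction = r$principal_direction))
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_roi_catalog
#' @return `read_roi_catalog` returns a named list of [roi_spec()]s.
#' @export
read_roi_catalog <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(seq_len(nrow(raw)), function(i)
    roi_spec(raw$label[i], unlist(raw$center[i]), raw$radius[i],
             unlist(raw$principal_direction[i])))
  stats::setNames(out, vapply(out, `[[`, character(1), "label"))
}

#' Write a RAC ensemble to CSV (trials in rows, samples in columns)
#'
#' @param ensemble a [rac_ensemble()].
#' @param path CSV path; the header row carries the sample latencies.
#' @export
write_rac_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "rac_ensemble"))
  m <- as.data.frame(ensemble$data)
  names(m) <- sprintf("t%.1f", ensemble$times)
  utils::write.csv(cbind(roi = ensemble$roi, m), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rac_csv
#' @export
read_rac_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  times <- as.numeric(sub("^t", "", names(df)[-1]))
  rac_ensemble(as.matrix(df[, -1]), times, roi = df$roi[1])
}

#' Write an SNR series table to CSV
#'
#' @param snr_list named list of [compute_snr()] results.
#' @param path CSV path.
#' @export
write_snr_csv <- function(snr_list, path) {
  rows <- do.call(rbind, lapply(snr_list, function(s)
    data.frame(roi = s$roi, center_ms = s$centers, snr = s$snr)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Export located maxima to a CSV table
#'
#' @param maxima list of [locate_maximum()] results (one per field).
#' @param path CSV path.
#' @export
write_maxima_csv <- function(maxima, path) {
  rows <- do.call(rbind, lapply(seq_along(maxima), function(i) {
    m <- maxima[[i]]
    data.frame(field = i, x = m$position[1], y = m$position[2],
               z = m$position[3], value = m$value, tie = m$tie,
               degenerate = m$degenerate)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
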