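## File interfaces: multi-page TIFF movies with JSON sidecars, label
## maps, occupancy tables, JSON reports.

#' Write / read a calcium movie as multi-page TIFF + JSON sidecar
#'
#' Intensities are stored as 32-bit float pages scaled into [0, 1]
#' (the scale factor is recorded in the sidecar, so round trips are
#' lossless up to float precision). The sidecar
#' (\code{<path>.json}) carries \code{stimulus}, \code{onset_frame},
#' \code{frame_rate_hz} and \code{intensity_scale}.
#'
#' @param movie a \code{\link{calcium_movie}}.
#' @param path output TIFF path.
#' @return invisibly the path (write); a \code{calcium_movie} (read).
#' @export
write_movie_tiff <- function(movie, path) {
  .check(inherits(movie, "calcium_movie"), "movie must be a calcium_movie")
  lo <- min(movie$stack)
  hi <- max(movie$stack)
  scale <- max(hi - lo, 1e-12)
  pages <- lapply(seq_len(dim(movie$stack)[3]), function(t) {
    (movie$stack[, , t] - lo) / scale
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  sidecar <- list(stimulus = movie$stimulus,
                  onset_frame = movie$onset_frame,
                  frame_rate_hz = movie$frame_rate,
                  intensity_offset = lo, intensity_scale = scale)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  stack <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) {
    stack[, , t] <- pages[[t]] * meta$intensity_scale + meta$intensity_offset
  }
  calcium_movie(stack, meta$stimulus, meta$onset_frame, meta$frame_rate_hz)
}

#' Write a granule label map as 16-bit TIFF
#'
#' @param gmap a \code{\link{granule_map}}.
#' @param path output path.
#' @export
write_labels_tiff <- function(gmap, path) {
  .check(inherits(gmap, "granule_map"), "gmap must be a granule_map")
  tiff::writeTIFF(gmap$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Write an occupancy table as CSV
#'
#' @param occupancy animals x 4 occupancy matrix (canonical patch
#'   columns).
#' @param path output path.
#' @param condition optional condition label column.
#' @export
write_occupancy_csv <- function(occupancy, path, condition = NA) {
  d <- data.frame(animal_id = seq_len(nrow(occupancy)),
                  condition = condition, occupancy)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write a reliability estimate as a JSON report
#'
#' @param est a \code{"reliability_estimate"}.
#' @param path output path.
#' @export
write_reliability_json <- function(est, path) {
  .check(inherits(est, "reliability_estimate"),
         "est must be a reliability_estimate")
  report <- lapply(seq_along(est$score), function(i) {
    list(class = names(est$score)[i], score = est$score[[i]],
         ci95 = as.numeric(est$ci95[, i]), n_repeats = est$n_repeats)
  })
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
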