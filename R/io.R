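#' Read and write geometry/crystal configuration and frame stacks
#'
#' Configurations are single JSON files whose keys mirror the
#' [detector_geometry()] and [crystal_frame()] fields.  Frame stacks are
#' stored as plain text: a `frames.csv` index (phi_start, phi_width,
#' scale_factor) plus one whitespace-separated matrix file per frame,
#' with an optional parallel mask file.
#'
#' @name config-io
NULL

#' @rdname config-io
#' @param geometry a [detector_geometry()]
#' @param crystal a [crystal_frame()]
#' @param path output JSON path
#' @export
write_config <- function(geometry, crystal, path) {
  cfg <- list(geometry = unclass(geometry),
              crystal = list(cell = crystal$cell,
                             spacegroup = crystal$spacegroup,
                             orientation = crystal$orientation))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config-io
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- cfg$geometry
  list(geometry = detector_geometry(
         distance = g$distance, pixel_size = g$pixel_size,
         n_fast = g$n_fast, n_slow = g$n_slow,
         beam_center = g$beam_center, wavelength = g$wavelength,
         polarization_fraction = g$polarization_fraction,
         polarization_plane_normal = g$polarization_plane_normal,
         rotation_axis = g$rotation_axis),
       crystal = crystal_frame(cfg$crystal$cell, cfg$crystal$spacegroup,
                               orientation = matrix(unlist(cfg$crystal$orientation),
                                                    3, 3)))
}

#' Write a frame stack as plain text
#'
#' @param frames list of [diffraction_frame()]s
#' @param dir output directory (created if needed)
#' @export
write_frames <- function(frames, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(frame = seq_along(frames),
                    phi_start = vapply(frames, `[[`, 0, "phi_start"),
                    phi_width = vapply(frames, `[[`, 0, "phi_width"),
                    scale_factor = vapply(frames, `[[`, 0, "scale_factor"))
  write.csv(idx, file.path(dir, "frames.csv"), row.names = FALSE)
  for (i in seq_along(frames)) {
    write(t(frames[[i]]$pixels), file.path(dir, sprintf("frame_%04d.txt", i)),
          ncolumns = ncol(frames[[i]]$pixels))
    if (!all(frames[[i]]$valid_mask))
      write(t(frames[[i]]$valid_mask * 1L),
            file.path(dir, sprintf("mask_%04d.txt", i)),
            ncolumns = ncol(frames[[i]]$valid_mask))
  }
  invisible(dir)
}

#' Read a frame stack written by [write_frames()]
#'
#' @param dir directory containing `frames.csv`
#' @return list of [diffraction_frame()]s
#' @export
read_frames <- function(dir) {
  idx <- read.csv(file.path(dir, "frames.csv"))
  lapply(seq_len(nrow(idx)), function(i) {
    px <- as.matrix(read.table(file.path(dir, sprintf("frame_%04d.txt", i))))
    dimnames(px) <- NULL
    mf <- file.path(dir, sprintf("mask_%04d.txt", i))
    vm <- if (file.exists(mf)) {
      m <- as.matrix(read.table(mf)) == 1
      dimnames(m) <- NULL
      m
    } else NULL
    diffraction_frame(px, valid_mask = vm, phi_start = idx$phi_start[i],
                      phi_width = idx$phi_width[i],
                      scale_factor = idx$scale_factor[i])
  })
}
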