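# Reading and writing colony movies as 16-bit label masks + sidecar files.

#' Write a generated colony movie to disk
#'
#' Writes one 16-bit TIFF label mask per frame (`frame_0001.tif`, ...), a
#' `truth.csv` (frame, label, track, parent, chain), the division events,
#' and `meta.yaml` / `config.yaml` echoing the generator parameters.
#'
#' @param run output of [grow_rod_colony()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_colony_frames <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (f in seq_along(run$frames)) {
    fr <- run$frames[[f]]
    # tiff wants [row, col] = [y, x] with values in [0, 1]
    m <- t(fr$mask) / 65535
    tiff::writeTIFF(m, file.path(dir, sprintf("frame_%04d.tif", f)),
                    bits.per.sample = 16)
  }
  utils::write.csv(run$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  utils::write.csv(run$divisions, file.path(dir, "divisions.csv"),
                   row.names = FALSE)
  cfg <- run$config
  class(cfg) <- NULL
  yaml::write_yaml(
    list(
      pixel_size = cfg$pixel_size, frame_interval = cfg$frame_interval,
      times = run$times,
      origin = as.numeric(run$frames[[1]]$origin)
    ),
    file.path(dir, "meta.yaml")
  )
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a colony movie from a mask directory
#'
#' Accepts the layout written by [write_colony_frames()]: numbered TIFF (or
#' PNG) label masks plus `meta.yaml` holding `pixel_size` and either
#' per-frame `times` or a `frame_interval`.
#'
#' @param dir directory of masks.
#' @return list of `colony_frame`s.
#' @export
read_colony_masks <- function(dir) {
  meta_path <- file.path(dir, "meta.yaml")
  if (!file.exists(meta_path)) stop("meta.yaml not found in ", dir)
  meta <- yaml::read_yaml(meta_path)
  files <- sort(list.files(dir, pattern = "\\.(tif|tiff|png)$",
                           full.names = TRUE))
  if (!length(files)) stop("no mask images found in ", dir)
  origin <- if (!is.null(meta$origin)) as.numeric(meta$origin) else c(0, 0)
  lapply(seq_along(files), function(f) {
    raw <- if (grepl("png$", files[f])) {
      png::readPNG(files[f])
    } else {
      tiff::readTIFF(files[f])
    }
    mask <- t(round(raw * 65535))
    storage.mode(mask) <- "integer"
    t_f <- if (!is.null(meta$times)) meta$times[f] else
      (f - 1) * meta$frame_interval
    colony_frame(mask, meta$pixel_size, time = t_f, origin = origin)
  })
}
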