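# Reading and writing stimulus ensembles, architecture specs, weight sets
# and modulation profiles.

#' Read a grayscale image from PNG or TIFF
#'
#' 8-/16-bit images arrive rescaled to [0, 1]; RGB(A) images are averaged
#' over their color channels.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`
#' @return numeric matrix
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) {
        stop("reading TIFF requires the 'tiff' package", call. = FALSE)
      }
      tiff::readTIFF(path)
    },
    stop(sprintf("unsupported image format '.%s'", ext), call. = FALSE))
  if (length(dim(img)) == 3) {
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE],
                 c(1, 2), mean)
  }
  img
}

#' Write a grayscale image as PNG
#'
#' Values are clipped to [0, 1] and quantized to 8 bits.
#' @param image numeric matrix
#' @param path output path
#' @export
write_image <- function(image, path) {
  check_image(image)
  png::writePNG(pmin(pmax(image, 0), 1), path, dpi = NULL)
  invisible(path)
}

#' Write a texture ensemble as PNG files plus a JSON manifest
#'
#' Layout: `family_<f>/sample_<s>_tex.png` and `..._noise.png` under
#' `dir`, with `manifest.json` recording family, sample, type, relative
#' path and the preprocessing provenance. Pixel values are clipped to
#' [0, 1] and quantized to 8-bit PNG, so a written-and-reread ensemble
#' matches to about 2e-3.
#'
#' @param ensemble a `texture_ensemble`
#' @param dir output directory (created if needed)
#' @return the manifest as a data frame, invisibly
#' @export
write_ensemble <- function(ensemble, dir) {
  stopifnot(inherits(ensemble, "texture_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (fam in ensemble$families) {
    fdir <- file.path(dir, sprintf("family_%d", fam$family_id))
    dir.create(fdir, showWarnings = FALSE)
    for (s in seq_along(fam$samples)) {
      for (type in c("tex", "noise")) {
        rel <- file.path(sprintf("family_%d", fam$family_id),
                         sprintf("sample_%d_%s.png", s, type))
        write_image(fam$samples[[s]][[type]], file.path(dir, rel))
        rows[[length(rows) + 1L]] <- data.frame(
          family = fam$family_id, sample = s, type = type, path = rel)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  jsonlite::write_json(
    list(provenance = ensemble$provenance, image_side = ensemble$image_side,
         images = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a texture ensemble written by [write_ensemble()]
#'
#' @param dir directory containing `manifest.json`
#' @return a `texture_ensemble`
#' @export
read_ensemble <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  images <- man$images
  fams <- sort(unique(images$family))
  fam_out <- lapply(fams, function(f) {
    sub <- images[images$family == f, ]
    ns <- sort(unique(sub$sample))
    samples <- lapply(ns, function(s) {
      list(tex = read_image(file.path(dir,
             sub$path[sub$sample == s & sub$type == "tex"])),
           noise = read_image(file.path(dir,
             sub$path[sub$sample == s & sub$type == "noise"])))
    })
    list(family_id = f, samples = samples)
  })
  structure(list(families = fam_out, image_side = man$image_side,
                 provenance = man$provenance),
            class = "texture_ensemble")
}

#' Read per-family naturalistic texture images from a directory tree
#'
#' Expects `family_<f>/` subdirectories of PNG/TIFF files (any naming);
#' used to feed externally generated textures into [build_ensemble()].
#'
#' @param dir root directory
#' @return list of families (lists of matrices) with `family_id` attributes
#' @export
read_texture_images <- function(dir) {
  fdirs <- list.dirs(dir, recursive = FALSE)
  fdirs <- fdirs[grepl("^family_", basename(fdirs))]
  if (length(fdirs) == 0) stop("no family_<f> subdirectories found",
                               call. = FALSE)
  ids <- as.integer(sub("^family_", "", basename(fdirs)))
  ord <- order(ids)
  lapply(ord, function(i) {
    files <- sort(list.files(fdirs[i], pattern = "\\.(png|tif|tiff)$",
                             full.names = TRUE, ignore.case = TRUE))
    out <- lapply(files, read_image)
    attr(out, "family_id") <- ids[i]
    out
  })
}

#' Serialize an architecture specification to YAML
#'
#' @param spec an [architecture_spec()]
#' @param path output path (`.yaml`)
#' @export
write_architecture_spec <- function(spec, path) {
  stopifnot(inherits(spec, "architecture_spec"))
  obj <- list(input_channels = spec$input_channels,
              layers = lapply(names(spec$layers), function(nm) {
                c(list(name = nm), unclass(spec$layers[[nm]]))
              }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read an architecture specification from YAML
#'
#' @param path path written by [write_architecture_spec()]
#' @return an [architecture_spec()]
#' @export
read_architecture_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  layers <- lapply(obj$layers, function(l) {
    switch(l$kind,
      conv = layer_conv(l$n_filters, l$kernel_side, l$stride, l$pad),
      relu = layer_relu(),
      maxpool = layer_maxpool(l$window, l$stride),
      lrn = layer_lrn(l$k, l$alpha, l$beta, l$m),
      stop(sprintf("unknown layer kind '%s'", l$kind), call. = FALSE))
  })
  architecture_spec(layers, input_channels = obj$input_channels,
                    names = vapply(obj$layers, `[[`, character(1), "name"))
}

#' Save / load a weight set
#'
#' Portable container: little-endian doubles in `<stem>.bin` plus a JSON
#' header `<stem>.json` recording layer names, shapes, mode and seed.
#'
#' @param weights a `weight_set`
#' @param stem path stem (without extension)
#' @export
save_weight_set <- function(weights, stem) {
  stopifnot(inherits(weights, "weight_set"))
  header <- list(mode = attr(weights, "mode"), seed = attr(weights, "seed"),
                 layers = lapply(weights, dim))
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  for (nm in names(weights)) {
    writeBin(as.vector(weights[[nm]]), con, size = 8, endian = "little")
  }
  invisible(stem)
}

#' @rdname save_weight_set
#' @param stem path stem used by [save_weight_set()]
#' @return a `weight_set`
#' @export
load_weight_set <- function(stem) {
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  con <- file(paste0(stem, ".bin"), "rb")
  on.exit(close(con))
  ws <- list()
  for (nm in names(header$layers)) {
    sh <- unlist(header$layers[[nm]])
    ws[[nm]] <- array(readBin(con, "double", n = prod(sh), size = 8,
                              endian = "little"), dim = sh)
  }
  structure(ws, class = "weight_set", mode = header$mode,
            seed = as.integer(header$seed))
}

#' Export a modulation profile as CSV
#'
#' Long format: neuron id, family, modulation index, plus a `valid` flag.
#' @param profile a [modulation_profile()]
#' @param path output `.csv` path
#' @export
write_modulation_csv <- function(profile, path) {
  stopifnot(inherits(profile, "modulation_profile"))
  M <- profile$M
  df <- data.frame(
    neuron = rep(seq_len(nrow(M)), times = ncol(M)),
    family = rep(seq_len(ncol(M)), each = nrow(M)),
    modulation_index = as.vector(M),
    valid = rep(profile$valid, times = ncol(M)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a modulation profile from CSV written by [write_modulation_csv()]
#'
#' @param path `.csv` path
#' @return a [modulation_profile()]
#' @export
read_modulation_csv <- function(path) {
  df <- utils::read.csv(path)
  nn <- max(df$neuron); nf <- max(df$family)
  M <- matrix(NA_real_, nn, nf)
  M[cbind(df$neuron, df$family)] <- df$modulation_index
  modulation_profile(M)
}
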