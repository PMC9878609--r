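#' Read / write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti with validation. Phantom volumes use an
#' identity affine. Write-then-read round-trips are bit-exact for double and
#' integer data.
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @return `read_nifti`: list with `data` (array), `dims`, `n_dim`,
#'   `pixdim`; `write_nifti`: `path` invisibly.
#' @export
read_nifti <- function(path) {
  if (!file.exists(path)) stop_rsn("malformed_file", "no such file: %s", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e) stop_rsn("malformed_file",
                                               "cannot read %s: %s", path,
                                               conditionMessage(e)))
  data <- as.array(img)
  pd <- RNifti::pixdim(img)
  attributes(data) <- list(dim = dim(data))   # plain array, no image attrs
  list(data = data, dims = dim(data), n_dim = length(dim(data)), pixdim = pd)
}

#' @rdname read_nifti
#' @param volume numeric or integer array (3D or 4D).
#' @param datatype NIfTI storage type (`"auto"`, `"double"`, `"int16"`,
#'   `"uint8"`, ...).
#' @export
write_nifti <- function(volume, path, datatype = "auto") {
  if (!is.array(volume)) stop("volume must be an array")
  RNifti::writeNifti(volume, path, datatype = datatype)
  invisible(path)
}

#' Write / read a phantom atlas as NIfTI + TSV
#'
#' The atlas is persisted as an ROI-label volume (`<prefix>_rois.nii.gz`,
#' integer), a mask (`<prefix>_mask.nii.gz`, uint8), and a TSV mapping
#' `roi_id` to `network_name`. Any atlas in this format (e.g., a real
#' volumetric parcellation) can be read back.
#'
#' @param atlas a `phantom_atlas`.
#' @param prefix output path prefix.
#' @return prefix invisibly (`write_atlas`); a `phantom_atlas`
#'   (`read_atlas`).
#' @export
write_atlas <- function(atlas, prefix) {
  dir.create(dirname(prefix), recursive = TRUE, showWarnings = FALSE)
  write_nifti(atlas$roi_volume, paste0(prefix, "_rois.nii.gz"), "int32")
  write_nifti(array(as.integer(atlas$mask), dim = dim(atlas$mask)),
              paste0(prefix, "_mask.nii.gz"), "uint8")
  ni <- vapply(atlas$rois, `[[`, integer(1), "network_index")
  tab <- data.frame(roi_id = vapply(atlas$rois, `[[`, integer(1), "roi_id"),
                    network_name = atlas$networks[ni])
  utils::write.table(tab, paste0(prefix, "_networks.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(prefix)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(prefix) {
  roi_vol <- read_nifti(paste0(prefix, "_rois.nii.gz"))$data
  mask <- read_nifti(paste0(prefix, "_mask.nii.gz"))$data > 0
  tab <- utils::read.delim(paste0(prefix, "_networks.tsv"))
  networks <- unique(tab$network_name)
  rois <- lapply(seq_len(nrow(tab)), function(i) {
    list(roi_id = tab$roi_id[i],
         network_index = match(tab$network_name[i], networks),
         voxels = which(roi_vol == tab$roi_id[i]))
  })
  storage.mode(roi_vol) <- "integer"
  network_volume <- array(0L, dim = dim(roi_vol))
  for (r in rois) network_volume[r$voxels] <- r$network_index
  structure(list(grid_shape = dim(roi_vol), mask = array(mask, dim(roi_vol)),
                 networks = networks, rois = rois, roi_volume = roi_vol,
                 network_volume = network_volume),
            class = "phantom_atlas")
}

#' Write a scan as 4D NIfTI (+ JSON sidecar)
#' @param scan a `bold_scan`.
#' @param path output `.nii.gz` path.
#' @param sidecar extra fields for the JSON sidecar.
#' @return `path` invisibly.
#' @export
write_scan <- function(scan, path, sidecar = list()) {
  write_nifti(scan$data, path)
  write_sidecar(path, c(list(subject_id = scan$subject_id, tr = scan$tr),
                        sidecar))
  invisible(path)
}

#' @rdname write_scan
#' @param mask logical mask to attach (read separately from the data file).
#' @export
read_scan <- function(path, mask = NULL) {
  nf <- read_nifti(path)
  if (nf$n_dim != 4) stop("expected a 4D scan")
  sc <- read_sidecar(path)
  if (is.null(mask)) mask <- apply(nf$data != 0, 1:3, any)
  structure(list(data = nf$data, tr = sc$tr %||% 1,
                 mask = mask, subject_id = sc$subject_id %||% basename(path)),
            class = "bold_scan")
}

#' Write probability or group maps as 4D NIfTI with a JSON sidecar
#'
#' The 4th axis indexes networks; the sidecar lists network names in order.
#'
#' @param pm a `probability_maps` or `group_maps`.
#' @param prefix output path prefix.
#' @param networks character vector of network names.
#' @return prefix invisibly.
#' @export
write_probability_maps <- function(pm, prefix, networks = NULL) {
  if (inherits(pm, "group_maps")) {
    for (what in c("mean", "std", "snr"))
      write_nifti(pm[[what]], paste0(prefix, "_", what, ".nii.gz"))
    write_sidecar(paste0(prefix, "_mean.nii.gz"),
                  list(networks = networks, n_subjects = pm$n_subjects))
  } else {
    write_nifti(pm$probs, paste0(prefix, "_probs.nii.gz"))
    write_sidecar(paste0(prefix, "_probs.nii.gz"),
                  list(networks = networks, subject_id = pm$subject_id))
  }
  invisible(prefix)
}

#' Write a segmentation as integer NIfTI
#' @param seg a `segmentation_volume`.
#' @param path output path.
#' @return `path` invisibly.
#' @export
write_segmentation <- function(seg, path) {
  write_nifti(seg$labels, path, "int32")
  write_sidecar(path, list(threshold = seg$threshold))
  invisible(path)
}

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

write_sidecar <- function(path, fields) {
  fields <- fields[!vapply(fields, is.null, logical(1))]
  jsonlite::write_json(fields, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(NULL)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(list())
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Export a connectivity matrix or robustness curve as TSV
#' @param x a `conn_matrix` or `robustness_curve` (any data.frame works).
#' @param path output TSV path.
#' @return `path` invisibly.
#' @export
export_tsv <- function(x, path) {
  if (inherits(x, "conn_matrix")) {
    x <- as.data.frame(x$matrix)
  }
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
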