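#' Toy atlas label volume
#'
#' Builds a small integer label volume by slicing the x-axis into
#' contiguous bands, one region per band — a desk-scale stand-in for a
#' white-matter atlas in tests and examples.
#'
#' @param dims Integer vector of length 3 (x, y, z).
#' @param n_regions Number of regions (`>= 1`).
#' @return A 3-D integer array of region codes `1:n_regions`.
#' @export
toy_label_volume <- function(dims = c(12L, 12L, 6L), n_regions = 3L) {
  stopifnot(length(dims) == 3L, n_regions >= 1L, dims[1L] >= n_regions)
  bands <- as.integer(ceiling(seq_len(dims[1L]) * n_regions / dims[1L]))
  array(rep(bands, times = prod(dims[2:3])), dim = dims)
}

#' Generate a synthetic voxel dataset with known DVR associations
#'
#' For a designated fraction of voxels in each atlas region, the metric
#' value across subjects is `intercept + slope * DVR + noise`; the
#' remaining voxels are pure noise around the intercept. The ground-truth
#' association mask is returned so recovery of significant voxels can be
#' scored exactly.
#'
#' @param subject_dvr Per-subject DVR values (length `>= 4`).
#' @param label_volume 3-D integer array of region codes (`0` = outside
#'   the analysis mask).
#' @param frac_assoc Fraction of associated voxels per region: a single
#'   number, or a named vector keyed by region code.
#' @param slope,intercept Linear association parameters.
#' @param noise_sd SD of i.i.d. voxel noise.
#' @param metric Name of the simulated metric (e.g. `"FA"`).
#' @param region_names Optional tibble with columns `label`, `region`;
#'   defaults to `region <k>`.
#' @param seed Integer seed.
#' @return An object of class `voxel_dataset`: list with `volumes` (4-D
#'   array, subject as 4th axis), `mask`, `labels`, `region_names`,
#'   `truth` (logical 3-D ground-truth association mask), `dvr`, `metric`.
#' @export
generate_voxel_dataset <- function(subject_dvr, label_volume,
                                   frac_assoc = 0.5, slope = 1,
                                   intercept = 0, noise_sd = 1,
                                   metric = "FA", region_names = NULL,
                                   seed = NULL) {
  n_subj <- length(subject_dvr)
  if (n_subj < 4L) {
    dvr_abort("Need at least 4 subjects (correlation unstable below that).",
              "dvr_too_few_cases")
  }
  dims <- dim(label_volume)
  if (length(dims) != 3L) dvr_abort("`label_volume` must be 3-D.",
                                    "dvr_bad_volume")
  labels <- sort(unique(as.integer(label_volume[label_volume > 0])))
  if (is.null(names(frac_assoc))) {
    frac_assoc <- setNames(rep(frac_assoc[1L], length(labels)),
                           as.character(labels))
  }
  if (any(frac_assoc < 0 | frac_assoc > 1)) {
    dvr_abort("`frac_assoc` must lie in [0, 1].", "dvr_bad_frac")
  }
  if (is.null(region_names)) {
    region_names <- tibble(label = labels,
                           region = paste("region", labels))
  }
  with_seed_if(seed, {
    truth <- array(FALSE, dims)
    for (lb in labels) {
      vox <- which(label_volume == lb)
      n_assoc <- round(frac_assoc[[as.character(lb)]] * length(vox))
      if (n_assoc > 0L) truth[sample(vox, n_assoc)] <- TRUE
    }
    n_vox <- prod(dims)
    flat <- matrix(rnorm(n_vox * n_subj, sd = noise_sd), n_vox, n_subj)
    flat <- flat + intercept
    assoc_idx <- which(as.vector(truth))
    if (length(assoc_idx) > 0L) {
      flat[assoc_idx, ] <- flat[assoc_idx, ] +
        matrix(slope * subject_dvr, length(assoc_idx), n_subj, byrow = TRUE)
    }
    volumes <- array(flat, c(dims, n_subj))
    structure(
      list(volumes = volumes, mask = label_volume > 0,
           labels = label_volume, region_names = region_names,
           truth = truth, dvr = as.numeric(subject_dvr), metric = metric),
      class = "voxel_dataset")
  })
}

#' @export
print.voxel_dataset <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("<voxel_dataset> %s: %d x %d x %d voxels, %d subjects, %d regions\n",
              x$metric, d[1L], d[2L], d[3L], d[4L],
              nrow(x$region_names)))
  invisible(x)
}

#' Voxelwise Pearson correlation of a metric with DVR
#'
#' Correlates each masked voxel's metric values across subjects with the
#' per-subject DVR, returning Pearson r and two-sided p maps. Voxels with
#' zero variance across subjects are excluded (`NA`).
#'
#' @param dvr Per-subject DVR vector (length = number of volumes).
#' @param volumes 4-D array (x, y, z, subject) or a `voxel_dataset` (then
#'   `dvr` defaults to its stored vector).
#' @param mask Logical 3-D analysis mask; defaults to all voxels (or the
#'   dataset's mask).
#' @return A list of class `voxel_corr_map` with 3-D arrays `r`, `p` and
#'   `n_excluded` (count of zero-variance voxels inside the mask).
#' @export
voxel_corr_map <- function(dvr, volumes = NULL, mask = NULL) {
  if (inherits(dvr, "voxel_dataset")) {
    ds <- dvr
    dvr <- ds$dvr; volumes <- ds$volumes; mask <- mask %||% ds$mask
  }
  d <- dim(volumes)
  if (length(d) != 4L) dvr_abort("`volumes` must be a 4-D array.",
                                 "dvr_bad_volume")
  n_subj <- d[4L]
  if (length(dvr) != n_subj) {
    dvr_abort("Subject count mismatch between `dvr` and `volumes`.",
              "dvr_length_mismatch")
  }
  if (n_subj < 4L) dvr_abort("Need at least 4 subjects.", "dvr_too_few_cases")
  if (is.null(mask)) mask <- array(TRUE, d[1:3])

  flat <- matrix(volumes, prod(d[1:3]), n_subj)
  midx <- which(as.vector(mask))
  V <- flat[midx, , drop = FALSE]
  Vc <- V - rowMeans(V)
  g <- dvr - mean(dvr)
  ssv <- rowSums(Vc^2)
  ok <- ssv > 0
  r_v <- rep(NA_real_, length(midx))
  r_v[ok] <- (Vc[ok, , drop = FALSE] %*% g) / sqrt(ssv[ok] * sum(g^2))
  r_v[ok] <- pmin(1, pmax(-1, r_v[ok]))
  df <- n_subj - 2L
  t_v <- r_v * sqrt(df / pmax(1 - r_v^2, .Machine$double.eps))
  p_v <- 2 * pt(-abs(t_v), df)
  p_v[ok & abs(r_v) >= 1] <- 0

  rmap <- pmap <- array(NA_real_, d[1:3])
  rmap[midx] <- r_v
  pmap[midx] <- p_v
  structure(list(r = rmap, p = pmap, n_excluded = sum(!ok),
                 n_subjects = n_subj),
            class = "voxel_corr_map")
}

#' Threshold a voxelwise p-map into a significance mask
#'
#' @param corr_map A `voxel_corr_map` (or a bare 3-D p-value array).
#' @param alpha Significance level in `(0, 1)`.
#' @param method `"uncorrected"` (voxelwise p < alpha) or `"bh_fdr"`
#'   (Benjamini–Hochberg across masked voxels).
#' @return Logical 3-D mask (`FALSE` at excluded/`NA` voxels), with
#'   attributes `alpha` and `method` recording the thresholding
#'   provenance.
#' @export
significant_mask <- function(corr_map, alpha = 0.05,
                             method = c("uncorrected", "bh_fdr")) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) dvr_abort("`alpha` must be in (0, 1).",
                                          "dvr_bad_alpha_level")
  pmap <- if (inherits(corr_map, "voxel_corr_map")) corr_map$p else corr_map
  idx <- which(!is.na(pmap))
  if (length(idx) == 0L) dvr_abort("Empty p-map.", "dvr_empty_map")
  p <- pmap[idx]
  pass <- if (method == "bh_fdr") p.adjust(p, "BH") < alpha else p < alpha
  mask <- array(FALSE, dim(pmap))
  mask[idx[pass]] <- TRUE
  structure(mask, alpha = alpha, method = method)
}

#' Per-region significant-voxel counts and percentages
#'
#' Tallies a significance mask over atlas regions: per-region counts,
#' percentage of the region's voxels that are significant, a whole-mask
#' totals row, and a flag for regions whose percentage exceeds
#' `highlight_pct` (conventionally 30%).
#'
#' @param mask Logical 3-D significance mask.
#' @param labels 3-D integer label volume (0 = outside analysis mask).
#' @param region_names Tibble with columns `label`, `region` naming every
#'   label present in `labels`.
#' @param highlight_pct Highlight threshold, percent.
#' @return A tibble of class `dvr_region_table` with columns `region`,
#'   `n_voxels` (region size), `n_significant`, `pct`, `highlight`; the
#'   final row (`region = "Whole mask"`) totals every labelled voxel.
#' @export
region_table <- function(mask, labels, region_names = NULL,
                         highlight_pct = 30) {
  if (!all(dim(mask) == dim(labels))) {
    dvr_abort("`mask` and `labels` dimensions differ.", "dvr_bad_volume")
  }
  present <- sort(unique(as.integer(labels[labels > 0])))
  if (is.null(region_names)) {
    region_names <- tibble(label = present, region = paste("region", present))
  }
  missing_names <- setdiff(present, region_names$label)
  if (length(missing_names) > 0L) {
    dvr_abort(paste0("Label(s) present in the volume but missing from ",
                     "`region_names`: ", paste(missing_names, collapse = ", ")),
              "dvr_unknown_label")
  }
  rows <- purrr::map(present, function(lb) {
    in_region <- labels == lb
    size <- sum(in_region)
    n_sig <- sum(mask & in_region)
    tibble(region = region_names$region[region_names$label == lb],
           n_voxels = size, n_significant = n_sig,
           pct = 100 * n_sig / size)
  })
  out <- dplyr::bind_rows(rows)
  total_size <- sum(labels > 0)
  total_sig <- sum(mask & labels > 0)
  out <- dplyr::bind_rows(out, tibble(
    region = "Whole mask", n_voxels = total_size, n_significant = total_sig,
    pct = 100 * total_sig / total_size))
  out$highlight <- out$pct > highlight_pct & out$region != "Whole mask"
  structure(out, highlight_pct = highlight_pct,
            class = c("dvr_region_table", class(out)))
}

#' Per-subject mean of a metric over a mask
#'
#' Reduces each subject's volume to a scalar — its mean over the masked
#' voxels — so that group statistics (e.g. [group_table()] rows) can be
#' computed over the significant voxels only.
#'
#' @param volumes 4-D array (x, y, z, subject).
#' @param mask Logical 3-D mask, nonempty.
#' @return Numeric vector, one value per subject.
#' @export
subject_mean_over_mask <- function(volumes, mask) {
  d <- dim(volumes)
  if (length(d) != 4L || !all(dim(mask) == d[1:3])) {
    dvr_abort("`volumes` must be 4-D and match `mask` dimensions.",
              "dvr_bad_volume")
  }
  if (!any(mask)) dvr_abort("Empty mask.", "dvr_empty_mask")
  flat <- matrix(volumes, prod(d[1:3]), d[4L])
  colMeans(flat[which(as.vector(mask)), , drop = FALSE])
}

#' @method autoplot dvr_region_table
#' @export
autoplot.dvr_region_table <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$region != "Whole mask")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$region, .data$pct),
                                   y = .data$pct, fill = .data$highlight)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = attr(object, "highlight_pct"),
                        linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#b2182b")) +
    ggplot2::labs(x = NULL, y = "Significant voxels (%)",
                  title = "Per-region DVR-associated voxels") +
    ggplot2::theme_minimal()
}

#' Write / read a voxel dataset as NIfTI with a JSON sidecar
#'
#' Writes the per-subject metric volumes (4-D), the analysis mask and the
#' label volume as NIfTI files, plus a JSON sidecar holding the DVR
#' vector, region names and (for synthetic data) the ground-truth
#' association mask indices.
#'
#' @param dataset A `voxel_dataset`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `write_voxel_dataset()` the (invisible) vector of file paths;
#'   `read_voxel_dataset()` the reconstructed `voxel_dataset`.
#' @export
write_voxel_dataset <- function(dataset, dir, prefix = dataset$metric) {
  stopifnot(inherits(dataset, "voxel_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    volumes = file.path(dir, paste0(prefix, "_volumes.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_labels.nii.gz")),
    sidecar = file.path(dir, paste0(prefix, "_truth.json")))
  RNifti::writeNifti(dataset$volumes, paths[["volumes"]])
  RNifti::writeNifti(dataset$mask * 1L, paths[["mask"]])
  RNifti::writeNifti(dataset$labels, paths[["labels"]])
  sidecar <- list(metric = dataset$metric, dvr = dataset$dvr,
                  region_names = dataset$region_names,
                  truth_idx = which(as.vector(dataset$truth)))
  atomic_write(paths[["sidecar"]], function(tmp) {
    jsonlite::write_json(sidecar, tmp, auto_unbox = TRUE, digits = NA)
  })
  invisible(paths)
}

#' @rdname write_voxel_dataset
#' @param paths Named paths as returned by [write_voxel_dataset()].
#' @export
read_voxel_dataset <- function(paths) {
  volumes <- array(as.numeric(RNifti::readNifti(paths[["volumes"]])),
                   dim = dim(RNifti::readNifti(paths[["volumes"]])))
  mask_img <- RNifti::readNifti(paths[["mask"]])
  labels_img <- RNifti::readNifti(paths[["labels"]])
  sidecar <- jsonlite::read_json(paths[["sidecar"]], simplifyVector = TRUE)
  dims <- dim(volumes)[1:3]
  truth <- array(FALSE, dims)
  truth[sidecar$truth_idx] <- TRUE
  structure(
    list(volumes = volumes,
         mask = array(as.integer(mask_img) > 0, dims),
         labels = array(as.integer(labels_img), dims),
         region_names = as_tibble(sidecar$region_names),
         truth = truth, dvr = as.numeric(sidecar$dvr),
         metric = sidecar$metric),
    class = "voxel_dataset")
}
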