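#' Gene panel and expression-overlap analysis
#'
#' The decoding step of the pipeline: transport significant FA clusters
#' into expression space, pool each gene's expression values over the
#' clusters of a contrast, compare them to the gene's values over the
#' entire FA skeleton with a rank-sum test, call overexpressed genes per
#' contrast at raw p < 0.05, and report which genes are exclusive to one
#' contrast.
#'
#' @name expression_overlap
NULL

#' Load the deletion gene panel
#'
#' Reads a TSV with columns `gene_symbol`, `gene_name`, `aliases`,
#' `plane`, `experiment_id` (empty id = no expression map available). The
#' packaged default is the 27-gene deletion panel, of which one member
#' (Prrt2) has no atlas experiment, leaving 26 usable maps.
#'
#' @param path TSV path; `NULL` loads the packaged panel.
#' @return A `gene_panel` data.frame with a logical `available` column.
#' @export
load_gene_panel <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "gene_panel_16p11.tsv",
                        package = "skelex", mustWork = TRUE)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("gene_symbol", "gene_name", "aliases", "plane", "experiment_id")
  if (!all(need %in% names(d)))
    stop("malformed panel: need columns ", paste(need, collapse = ", "))
  if (anyDuplicated(d$gene_symbol))
    stop("duplicate gene symbol(s): ",
         paste(unique(d$gene_symbol[duplicated(d$gene_symbol)]),
               collapse = ", "))
  if (any(d$gene_symbol == "")) stop("malformed panel: empty gene symbol")
  d$available <- trimws(d$experiment_id) != ""
  class(d) <- c("gene_panel", "data.frame")
  d
}

#' Load the published per-contrast gene lists
#'
#' The packaged fixture holds the four contrast gene lists
#' (`male_increase`, `male_decrease`, `female_increase`,
#' `female_decrease`); see the fixture's comment field for which parts of
#' the column assignment are reconstruction.
#'
#' @param path JSON path; `NULL` loads the packaged fixture.
#' @return Named list of four character vectors.
#' @export
load_contrast_gene_lists <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "contrast_genes_16p11.json",
                        package = "skelex", mustWork = TRUE)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  keys <- c("male_increase", "male_decrease",
            "female_increase", "female_decrease")
  if (!all(keys %in% names(obj)))
    stop("fixture must name the four contrast lists")
  obj[keys]
}

# nearest-voxel transport of 0-based linear voxel indices from a source
# grid through a transform into a target grid; returns a 0/1 mask volume
transport_voxels <- function(vox, source_grid, transform, target_grid) {
  src <- as_grid(source_grid)
  tgt <- as_grid(target_grid)
  out <- array(0, tgt$shape)
  if (length(vox)) {
    d <- src$shape
    ijk <- cbind(vox %% d[1], (vox %/% d[1]) %% d[2], vox %/% (d[1] * d[2]))
    w <- t(src$affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
    if (!is.null(transform)) w <- apply_transform(transform, w)
    tv <- round(t(solve(tgt$affine) %*% rbind(t(w), 1))[, 1:3, drop = FALSE])
    keep <- tv[, 1] >= 0 & tv[, 2] >= 0 & tv[, 3] >= 0 &
      tv[, 1] < tgt$shape[1] & tv[, 2] < tgt$shape[2] & tv[, 3] < tgt$shape[3]
    tv <- tv[keep, , drop = FALSE]
    out[tv + 1] <- 1
  }
  brain_volume(out, spacing = tgt$spacing, affine = tgt$affine)
}

#' Transport contrast clusters onto the expression grid
#'
#' Nearest-neighbour transport of every cluster voxel through the
#' composed diffusion-to-expression transform chain onto the expression
#' grid; every nonempty cluster contributes at least one voxel.
#'
#' @param clusters cluster list from [extract_clusters] (or a
#'   `contrast_result` whose clusters are set).
#' @param source_grid the diffusion-space grid the cluster voxel indices
#'   refer to ([brain_volume] or grid list).
#' @param chain transform chain from diffusion to expression space
#'   (`NULL` = identity, regridding only).
#' @param target_grid the expression grid.
#' @return A 0/1 mask [brain_volume] on the expression grid.
#' @export
map_clusters_to_expression_grid <- function(clusters, source_grid,
                                            chain = NULL, target_grid) {
  if (inherits(clusters, "contrast_result")) clusters <- clusters$clusters
  composed <- if (is.null(chain)) NULL else compose_chain(chain)
  vox <- unlist(lapply(clusters, `[[`, "voxels"))
  if (!length(vox)) warning("empty cluster list: empty mask")
  transport_voxels(as.integer(vox), source_grid, composed, target_grid)
}

#' Transport the skeleton mask onto the expression grid
#' @param skel an `fa_skeleton`.
#' @inheritParams map_clusters_to_expression_grid
#' @export
map_skeleton_to_expression_grid <- function(skel, chain = NULL,
                                            target_grid) {
  composed <- if (is.null(chain)) NULL else compose_chain(chain)
  transport_voxels(as.integer(skel$vox), skel$mean_fa, composed,
                   target_grid)
}

#' Extract expression values under a mask
#'
#' Values of the energy volume at mask voxels in raster order, excluding
#' the missing sentinel.
#'
#' @param energy a [brain_volume].
#' @param mask a 0/1 or logical [brain_volume] (or array) on the same
#'   grid.
#' @return Numeric vector of expression values.
#' @export
extract_sample <- function(energy, mask) {
  m <- if (inherits(mask, "brain_volume")) mask$data else mask
  if (!all(dim(m) == dim(energy$data))) stop("grid mismatch")
  sel <- (m != 0) & valid_mask(energy)
  vals <- energy$data[sel]
  if (!length(vals))
    stop("no valid voxels under the mask after missing-value exclusion")
  vals
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum (Mann-Whitney) test with midrank tie handling.
#' When the smaller sample has at most 8 observations (and the
#' enumeration is tractable) the p value is computed by exhaustive
#' enumeration of all group assignments of the midranks, which is exact
#' for tied data too; otherwise the normal approximation with
#' tie-corrected variance and continuity correction is used. Two-sided
#' by default.
#'
#' @param x,y numeric samples (both nonempty).
#' @param alternative `"two.sided"`, `"greater"` or `"less"` (x vs y).
#' @return `list(statistic, p_value, method)`; the statistic is the
#'   Mann-Whitney U of `x`.
#' @export
ranksum_test <- function(x, y,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stop("empty sample")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  use_exact <- min(nx, ny) <= 8 && choose(N, min(nx, ny)) <= 20000
  if (use_exact) {
    combos <- utils::combn(N, nx)
    Wperm <- colSums(matrix(r[combos], nrow = nx))
    mu <- nx * (N + 1) / 2
    eps <- 1e-9
    p <- switch(alternative,
      two.sided = mean(abs(Wperm - mu) >= abs(W - mu) - eps),
      greater = mean(Wperm >= W - eps),
      less = mean(Wperm <= W + eps))
    return(list(statistic = U, p_value = p, method = "exact enumeration"))
  }
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = FALSE, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "normal approximation")
}

#' Classify genes as overexpressed per contrast
#'
#' For each available gene and each contrast, pools the gene's expression
#' values over the contrast's clusters, compares them to the gene's
#' values over the entire FA skeleton with a two-sided rank-sum test, and
#' calls the direction from the medians. "Overexpressed" requires
#' p < alpha and cluster median above skeleton median; the raw-alpha
#' convention is the default, with Benjamini-Hochberg available per
#' contrast via `correction`.
#'
#' @param energy_maps named list of [brain_volume]s, one per gene.
#' @param cluster_masks named list of mask [brain_volume]s on the
#'   expression grid, one per contrast.
#' @param skeleton_mask skeleton mask [brain_volume] on the expression
#'   grid (the reference sample; cluster voxels included).
#' @param alpha significance threshold.
#' @param panel optional `gene_panel`; unavailable panel genes appear in
#'   the result with status `"no_map"`.
#' @param correction `"none"` (raw threshold) or `"BH"`.
#' @param pooling `"voxels"` pools the voxelwise values over all clusters
#'   of a contrast; `"cluster_means"` uses per-cluster means as the
#'   sample (requires a label-map `cluster_masks`, values 1..k).
#' @return A data.frame (one row per gene x contrast) with the rank-sum
#'   statistic, p value, medians and direction; per-contrast
#'   overexpressed gene lists are in `attr(, "overexpressed")`.
#' @export
classify_genes <- function(energy_maps, cluster_masks, skeleton_mask,
                           alpha = 0.05, panel = NULL,
                           correction = c("none", "BH"),
                           pooling = c("voxels", "cluster_means")) {
  correction <- match.arg(correction)
  pooling <- match.arg(pooling)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  rows <- list()
  for (contrast in names(cluster_masks)) {
    cmask <- cluster_masks[[contrast]]
    cm_data <- if (inherits(cmask, "brain_volume")) cmask$data else cmask
    has_clusters <- any(cm_data != 0)
    if (!has_clusters)
      warning("contrast '", contrast, "' has no cluster voxels; ",
              "empty gene list")
    for (gene in names(energy_maps)) {
      energy <- energy_maps[[gene]]
      if (!has_clusters) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, contrast = contrast, status = "no_clusters",
          n_cluster_voxels = 0L,
          n_skeleton_voxels = length(extract_sample(energy, skeleton_mask)),
          statistic = NA_real_, p_value = NA_real_,
          median_cluster = NA_real_, median_skeleton = NA_real_,
          direction = "none", stringsAsFactors = FALSE)
        next
      }
      skel_sample <- extract_sample(energy, skeleton_mask)
      if (pooling == "voxels") {
        clus_sample <- extract_sample(energy, cmask)
      } else {
        labs <- sort(unique(cm_data[cm_data != 0]))
        clus_sample <- vapply(labs, function(l)
          mean(extract_sample(energy, cm_data == l)), numeric(1))
      }
      ht <- ranksum_test(clus_sample, skel_sample)
      med_c <- stats::median(clus_sample)
      med_s <- stats::median(skel_sample)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, contrast = contrast, status = "tested",
        n_cluster_voxels = length(clus_sample),
        n_skeleton_voxels = length(skel_sample),
        statistic = ht$statistic, p_value = ht$p_value,
        median_cluster = med_c, median_skeleton = med_s,
        direction = "none", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(panel)) {
    for (gene in panel$gene_symbol[!panel$available]) {
      for (contrast in names(cluster_masks)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, contrast = contrast, status = "no_map",
          n_cluster_voxels = NA_integer_, n_skeleton_voxels = NA_integer_,
          statistic = NA_real_, p_value = NA_real_,
          median_cluster = NA_real_, median_skeleton = NA_real_,
          direction = "none", stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, rows)
  res$p_adjusted <- res$p_value
  for (contrast in unique(res$contrast)) {
    sel <- res$contrast == contrast & res$status == "tested"
    if (correction == "BH" && any(sel))
      res$p_adjusted[sel] <- stats::p.adjust(res$p_value[sel], "BH")
    sig <- sel & !is.na(res$p_adjusted) & res$p_adjusted < alpha
    res$direction[sig & res$median_cluster > res$median_skeleton] <- "over"
    res$direction[sig & res$median_cluster < res$median_skeleton] <- "under"
  }
  over <- lapply(split(res, res$contrast), function(d)
    sort(d$gene[d$direction == "over"]))
  attr(res, "overexpressed") <- over[names(cluster_masks)]
  attr(res, "alpha") <- alpha
  res
}

#' Contrast-exclusivity report
#'
#' For each contrast, the genes present in its list and absent from all
#' other contrast lists (stable alphabetical order), plus a gene-by-
#' contrast membership matrix.
#'
#' @param lists named list of per-contrast character gene lists.
#' @param panel optional `gene_panel`; listed symbols must then belong to
#'   the panel.
#' @return `list(lists, membership, exclusive)`.
#' @export
exclusivity_report <- function(lists, panel = NULL) {
  stopifnot(is.list(lists), length(lists) >= 2)
  if (!is.null(panel)) {
    unknown <- setdiff(unique(unlist(lists)), panel$gene_symbol)
    if (length(unknown))
      stop("symbol(s) not in panel: ", paste(unknown, collapse = ", "))
  }
  genes <- sort(unique(unlist(lists)))
  membership <- matrix(FALSE, length(genes), length(lists),
                       dimnames = list(genes, names(lists)))
  for (nm in names(lists)) membership[lists[[nm]], nm] <- TRUE
  exclusive <- lapply(names(lists), function(nm) {
    others <- unique(unlist(lists[setdiff(names(lists), nm)]))
    sort(setdiff(lists[[nm]], others))
  })
  names(exclusive) <- names(lists)
  list(lists = lapply(lists, sort), membership = membership,
       exclusive = exclusive)
}

#' Write the gene-overlap report
#'
#' Writes `gene_overlap.tsv` (one row per gene x contrast),
#' `table2_matrix.tsv` (a four-column matrix of overexpressed genes per
#' contrast) and `exclusivity.json`. Deterministic bytes given inputs.
#'
#' @param results data.frame from [classify_genes].
#' @param exclusivity list from [exclusivity_report].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(results, exclusivity, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  f1 <- file.path(dir, "gene_overlap.tsv")
  utils::write.table(results, f1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lists <- lapply(exclusivity$lists, sort)
  nmax <- max(c(1L, vapply(lists, length, integer(1))))
  mat <- vapply(lists, function(l) c(l, rep("", nmax - length(l))),
                character(nmax))
  mat <- matrix(mat, nrow = nmax, dimnames = list(NULL, names(lists)))
  f2 <- file.path(dir, "table2_matrix.tsv")
  utils::write.table(mat, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  f3 <- file.path(dir, "exclusivity.json")
  jsonlite::write_json(exclusivity[c("lists", "exclusive")], f3,
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(c(f1, f2, f3))
}
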