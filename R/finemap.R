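# Fine-mapping: imputation of founder-strain variants onto the DO sample,
# founder allele pattern (FAP) assignment and grouping, annotation
# overlap, and age/diet effect-size profiles for lead variants.
#
# A variant's FAP is the subset of founders carrying its minor allele
# (the allele carried by fewer founders), written as founder names joined
# by "/" in the canonical order. Grouping significant variants by FAP and
# scoring each group by its best member LOD concentrates the association
# signal on a small number of candidate haplotypes.

#' Construct a dosage matrix
#'
#' @param dosages N x V matrix of expected allele counts in `[0, 2]`.
#' @param map Data frame `marker`, `chrom`, `pos_bp` (V rows).
#' @return A `dosage_matrix` object.
#' @export
dosage_matrix <- function(dosages, map) {
  dosages <- as.matrix(dosages)
  stopifnot(nrow(map) == ncol(dosages))
  if (any(dosages < -1e-9 | dosages > 2 + 1e-9)) {
    stop_validation("dosages must lie in [0, 2]")
  }
  structure(list(dosages = pmin(pmax(dosages, 0), 2),
                 map = as.data.frame(map)),
            class = "dosage_matrix")
}

#' Read founder-strain genotypes from a VCF
#'
#' Expects a biallelic VCF with one sample per founder strain (sample
#' names matching [DO_FOUNDERS]). Returns per-variant alternate allele
#' counts per founder: 0 or 2 for the homozygous calls expected of inbred
#' strains, 1 for a heterozygous call (such variants are excluded from FAP
#' assignment), NA for missing.
#'
#' @param path Path to VCF (uncompressed or gzipped).
#' @return List with `counts` (V x 8 integer matrix, columns in canonical
#'   founder order) and `map` (`marker`, `chrom`, `pos_bp`, `ref`, `alt`).
#' @export
read_founder_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  missing_f <- setdiff(DO_FOUNDERS, colnames(gt))
  if (length(missing_f) > 0) {
    stop_format("VCF lacks founder sample(s): %s", paste(missing_f, collapse = ", "))
  }
  gt <- gt[, DO_FOUNDERS, drop = FALSE]
  count1 <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  counts <- apply(gt, 2, count1)
  fix <- vcfR::getFIX(v)
  map <- data.frame(marker = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                                    paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                                    fix[, "ID"]),
                    chrom = fix[, "CHROM"],
                    pos_bp = as.numeric(fix[, "POS"]),
                    ref = fix[, "REF"], alt = fix[, "ALT"],
                    stringsAsFactors = FALSE)
  list(counts = matrix(counts, ncol = 8,
                       dimnames = list(map$marker, DO_FOUNDERS)),
       map = map)
}

#' Impute untyped-variant dosages from founder probabilities
#'
#' For an untyped variant lying between two typed markers on the same
#' chromosome, the founder-of-origin probabilities at the variant are
#' linearly interpolated (in physical position) between the flanking
#' markers, and the expected dosage is the probability-weighted sum of the
#' founder allele counts: `dosage = sum_f p_f(position) * count_f`.
#' Variants outside the typed-marker span are skipped (count reported in
#' attribute `n_skipped`).
#'
#' @param fp A `founder_probs` object at typed markers.
#' @param founder_counts V_untyped x 8 matrix of founder alternate-allele
#'   counts (see [read_founder_vcf()]).
#' @param variant_map Data frame `marker`, `chrom`, `pos_bp` for the
#'   untyped variants (rows matching `founder_counts`).
#' @return A `dosage_matrix` over the imputable variants, with attribute
#'   `n_skipped`.
#' @export
impute_dosages <- function(fp, founder_counts, variant_map) {
  founder_counts <- as.matrix(founder_counts)
  stopifnot(ncol(founder_counts) == 8, nrow(variant_map) == nrow(founder_counts))
  n <- dim(fp$probs)[1]
  keep <- logical(nrow(variant_map))
  cols <- vector("list", nrow(variant_map))
  for (u in seq_len(nrow(variant_map))) {
    cc <- variant_map$chrom[u]
    typed <- which(fp$map$chrom == cc)
    if (length(typed) < 2) next
    tp <- fp$map$pos_bp[typed]
    ord <- order(tp); typed <- typed[ord]; tp <- tp[ord]
    pos <- variant_map$pos_bp[u]
    if (pos < tp[1] || pos > tp[length(tp)]) next
    i <- findInterval(pos, tp)
    i2 <- min(i + 1, length(tp))
    w <- if (tp[i2] == tp[i]) 0 else (pos - tp[i]) / (tp[i2] - tp[i])
    pmat <- (1 - w) * fp$probs[, typed[i], ] + w * fp$probs[, typed[i2], ]
    cnt <- founder_counts[u, ]
    if (anyNA(cnt)) next
    cols[[u]] <- as.vector(pmat %*% cnt)
    keep[u] <- TRUE
  }
  if (!any(keep)) stop_validation("no variants within the typed-marker span")
  D <- do.call(cbind, cols[keep])
  dimnames(D) <- list(dimnames(fp$probs)[[1]], variant_map$marker[keep])
  out <- dosage_matrix(D, variant_map[keep, c("marker", "chrom", "pos_bp")])
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Assign the founder allele pattern of a variant
#'
#' The minor allele is the one carried by fewer founders; the FAP label
#' joins the carrier founder names with `/` in canonical order. In a 4/4
#' split the side containing the earliest founder in canonical order
#' (AJ) is labeled. Variants with a heterozygous founder call or
#' monomorphic across founders get `NA`.
#'
#' @param founder_alleles Length-8 vector: alternate-allele counts per
#'   founder (0/2 homozygous, 1 heterozygous), in canonical founder
#'   order; or a character vector of alleles (e.g. `c("A","G",...)`).
#' @return FAP label string, or `NA_character_` (attribute `reason` says
#'   why).
#' @export
assign_fap <- function(founder_alleles) {
  if (is.character(founder_alleles)) {
    alleles <- unique(founder_alleles)
    if (length(alleles) == 1) {
      return(structure(NA_character_, reason = "monomorphic"))
    }
    if (length(alleles) > 2) {
      return(structure(NA_character_, reason = "multiallelic"))
    }
    carrier <- founder_alleles == alleles[1]
  } else {
    if (length(founder_alleles) != 8) stop_validation("need 8 founder alleles")
    if (anyNA(founder_alleles)) {
      return(structure(NA_character_, reason = "missing"))
    }
    if (any(founder_alleles == 1)) {
      return(structure(NA_character_, reason = "heterozygous founder"))
    }
    carrier <- founder_alleles == 2
    if (all(carrier) || !any(carrier)) {
      return(structure(NA_character_, reason = "monomorphic"))
    }
  }
  n_car <- sum(carrier)
  minor <- if (n_car < 8 - n_car) carrier
    else if (n_car > 8 - n_car) !carrier
    else if (carrier[1]) carrier else !carrier  # 4/4 tie: side containing AJ
  paste(DO_FOUNDERS[minor], collapse = "/")
}

#' Group significant variants by FAP and rank groups by LOD
#'
#' Partitions variants by FAP label (each variant belongs to exactly one
#' group), scores each group by the largest LOD among its members, and
#' ranks groups by that score (ties broken by member count, then label).
#'
#' @param variants Data frame with columns `marker`, `fap`, `lod`, and
#'   optionally `pos_bp`. Rows with `NA` fap are dropped.
#' @return A data frame of class `fap_groups`: `fap`, `rank`, `group_lod`,
#'   `n_members`, `span_start`, `span_end`; attribute `members` holds the
#'   marker ids per group.
#' @export
group_and_rank_faps <- function(variants) {
  variants <- variants[!is.na(variants$fap), , drop = FALSE]
  if (nrow(variants) == 0) stop_validation("no variants with assigned FAP")
  sp <- split(variants, variants$fap)
  df <- do.call(rbind, lapply(names(sp), function(lbl) {
    g <- sp[[lbl]]
    data.frame(fap = lbl,
               group_lod = max(g$lod),
               n_members = nrow(g),
               span_start = if (!is.null(g$pos_bp)) min(g$pos_bp) else NA_real_,
               span_end = if (!is.null(g$pos_bp)) max(g$pos_bp) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-df$group_lod, -df$n_members, df$fap)
  df <- df[ord, , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  df <- df[, c("fap", "rank", "group_lod", "n_members", "span_start", "span_end")]
  rownames(df) <- NULL
  attr(df, "members") <- lapply(sp, function(g) g$marker)[df$fap]
  class(df) <- c("fap_groups", "data.frame")
  df
}

#' Overlap variants with genes and regulatory elements
#'
#' Point-in-interval membership under the 0-based half-open convention: a
#' variant at position p hits `[start, end)` iff `start <= p < end`.
#'
#' @param variants Data frame with `chrom` and `pos_bp` (0-based
#'   positions).
#' @param annotations An `annotation_set` object.
#' @return The input with added columns `in_gene`, `gene_name`,
#'   `in_regulatory`, `tissue` (multiple hits joined with `,`).
#' @export
annotate_variants <- function(variants, annotations) {
  ann_chroms <- unique(c(annotations$genes$chrom, annotations$regulatory$chrom))
  var_chroms <- unique(variants$chrom)
  if (length(ann_chroms) > 0 && length(intersect(var_chroms, ann_chroms)) == 0) {
    stop_validation("chromosome names do not match annotations: %s",
                    paste(setdiff(var_chroms, ann_chroms), collapse = ", "))
  }
  hit_labels <- function(iv, label_col) {
    out_hit <- logical(nrow(variants))
    out_lab <- rep(NA_character_, nrow(variants))
    for (cc in unique(variants$chrom)) {
      vi <- which(variants$chrom == cc)
      ii <- which(iv$chrom == cc)
      if (length(ii) == 0) next
      # 0-based half-open [start, end) -> 1-based closed [start+1, end]
      ir <- IRanges::IRanges(start = iv$start[ii] + 1L, end = iv$end[ii])
      pts <- IRanges::IRanges(start = variants$pos_bp[vi] + 1L, width = 1L)
      ov <- IRanges::findOverlaps(pts, ir)
      if (length(ov) == 0) next
      qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
      labs <- tapply(iv[[label_col]][ii][sh], qh,
                     function(x) paste(unique(x), collapse = ","))
      out_hit[vi[as.integer(names(labs))]] <- TRUE
      out_lab[vi[as.integer(names(labs))]] <- as.character(labs)
    }
    list(hit = out_hit, lab = out_lab)
  }
  g <- hit_labels(annotations$genes, "name")
  r <- hit_labels(annotations$regulatory, "tissue")
  variants$in_gene <- g$hit
  variants$gene_name <- g$lab
  variants$in_regulatory <- r$hit
  variants$tissue <- r$lab
  variants
}

#' Age profile of a variant's effect sizes
#'
#' For each analysis age, fits the focal variant's fixed effects by GLS
#' under the age's fitted covariance and extracts the effect estimate and
#' standard error at the requested level: per founder allele, per diet
#' (minor-allele-by-diet), or per (founder, diet) pair. Mice lacking a
#' weight at an age are dropped from that cross-section; non-converged
#' ages yield missing entries.
#'
#' @param weight Mouse x age matrix of trend-filtered weights (NA where a
#'   mouse's span does not cover the age).
#' @param ages Analysis ages (columns of `weight`).
#' @param G A `founder_probs` or `dosage_matrix` object (rows matching
#'   mice).
#' @param v Variant index in `G`.
#' @param Z Environment matrix (rows matching mice), or a function of age
#'   returning one.
#' @param K Kinship matrix (this variant's LOCO kinship).
#' @param level `"founder"`, `"diet"`, or `"founder_diet"`.
#' @param diet_cols Diet columns of `Z` (diet levels).
#' @param vc_by_age Optional named list of pre-fit `variance_components`
#'   per age; fitted when absent.
#' @param ... Passed to [fit_gxemm()].
#' @return Data frame of class `effect_profile`: `age`, `term`,
#'   `estimate`, `se`.
#' @export
effect_profile <- function(weight, ages, G, v, Z, K, level = "founder",
                           diet_cols = NULL, vc_by_age = NULL, ...) {
  rows <- lapply(seq_along(ages), function(j) {
    y <- weight[, j]
    ok <- is.finite(y)
    if (sum(ok) < 10) return(NULL)
    Zj <- as.matrix(Z)[ok, , drop = FALSE]
    Xj <- fixed_effects_design(Zj)
    Kj <- unclass(K)[ok, ok]
    Gj <- subset_genotypes(G, ok)
    vc <- vc_by_age[[as.character(ages[j])]] %||%
      tryCatch(fit_gxemm(y[ok], Xj, Kj, Zj, ...), error = function(e) NULL)
    if (is.null(vc)) return(NULL)
    eff <- variant_effects(y[ok], Gj, v, Xj, Zj, Kj, vc,
                           level = if (level == "founder") "additive" else "diet",
                           diet_cols = diet_cols,
                           founder_effects = level %in% c("founder", "founder_diet"))
    cbind(age = ages[j], eff)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("effect_profile", "data.frame")
  out
}

# internal: row-subset a genotype container
subset_genotypes <- function(G, idx) {
  if (inherits(G, "founder_probs")) {
    structure(list(probs = G$probs[idx, , , drop = FALSE], map = G$map),
              class = "founder_probs")
  } else if (inherits(G, "dosage_matrix")) {
    structure(list(dosages = G$dosages[idx, , drop = FALSE], map = G$map),
              class = "dosage_matrix")
  } else {
    as.matrix(G)[idx, , drop = FALSE]
  }
}
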