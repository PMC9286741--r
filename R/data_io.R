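# Readers and writers for the package's tabular dialects and for standard
# genomic formats. Every downstream module consumes the domain objects
# constructed here (phenotype series, founder-probability arrays,
# environment designs, annotation sets), never raw files.

#' Read longitudinal phenotype series
#'
#' Reads a CSV of per-mouse body-weight measurements with columns
#' `mouse_id`, `age_days`, `weight_g` and returns one series per mouse,
#' sorted by age. Ages must be strictly increasing within a mouse (duplicate
#' (mouse, age) rows are rejected) and weights strictly positive.
#'
#' @param path Path to a CSV file.
#' @param source Provenance tag for the series, `"raw"` or `"trend_filtered"`.
#' @return A `bw_phenotypes` object: a data frame with columns `mouse_id`,
#'   `age_days`, `weight_g`, sorted by mouse then age, with attribute
#'   `source`.
#' @seealso [write_phenotypes()], [phenotype_series()]
#' @export
read_phenotypes <- function(path, source = c("raw", "trend_filtered")) {
  source <- match.arg(source)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "age_days", "weight_g")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format("phenotype file %s lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  phenotype_series(df$mouse_id, df$age_days, df$weight_g, source = source)
}

#' Construct a phenotype series collection
#'
#' @param mouse_id Mouse identifiers (one entry per measurement).
#' @param age_days Integer ages in days.
#' @param weight_g Positive weights in grams.
#' @param source `"raw"` or `"trend_filtered"`.
#' @return A `bw_phenotypes` data frame (see [read_phenotypes()]).
#' @export
phenotype_series <- function(mouse_id, age_days, weight_g,
                             source = c("raw", "trend_filtered")) {
  source <- match.arg(source)
  df <- data.frame(mouse_id = as.character(mouse_id),
                   age_days = as.integer(age_days),
                   weight_g = as.numeric(weight_g),
                   stringsAsFactors = FALSE)
  bad <- which(!is.finite(df$weight_g) | df$weight_g <= 0)
  if (length(bad) > 0) {
    stop_validation("non-positive or non-finite weight at row %d (mouse %s, age %d)",
                    bad[1], df$mouse_id[bad[1]], df$age_days[bad[1]])
  }
  df <- df[order(df$mouse_id, df$age_days), , drop = FALSE]
  dup <- duplicated(df[, c("mouse_id", "age_days")])
  if (any(dup)) {
    i <- which(dup)[1]
    stop_validation("duplicated measurement for mouse %s at age %d",
                    df$mouse_id[i], df$age_days[i])
  }
  rownames(df) <- NULL
  attr(df, "source") <- source
  class(df) <- c("bw_phenotypes", "data.frame")
  df
}

#' Write phenotype series to canonical CSV
#'
#' The canonical form (columns `mouse_id`, `age_days`, `weight_g`, rows
#' sorted by mouse then age) round-trips byte-identically through
#' [read_phenotypes()].
#'
#' @param phen A `bw_phenotypes` object.
#' @param path Output path.
#' @export
write_phenotypes <- function(phen, path) {
  utils::write.csv(as.data.frame(phen)[, c("mouse_id", "age_days", "weight_g")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a phenotype collection into per-mouse series
#'
#' @param phen A `bw_phenotypes` object.
#' @return Named list (by mouse id) of data frames with `age_days`, `weight_g`.
#' @export
split_by_mouse <- function(phen) {
  split(as.data.frame(phen)[, c("age_days", "weight_g")], phen$mouse_id)
}

# ---------------------------------------------------------------------------
# founder probabilities
# ---------------------------------------------------------------------------

#' Read founder-of-origin probabilities
#'
#' Reads the package's tabular dialect for founder-probability arrays: a CSV
#' with columns `mouse_id`, `marker`, `chrom`, `pos_bp` and one column per
#' founder in the canonical order ([DO_FOUNDERS]). Each row holds, for one
#' mouse at one marker, the probability that its alleles derive from each of
#' the eight founder lines; row sums must be within `tol` of 1 and are
#' renormalized to exactly unit L1 norm.
#'
#' Upstream haplotype-reconstruction tools (e.g. qtl2) store these arrays in
#' their own formats; [as_founder_probs()] converts an in-memory 3-d array.
#'
#' @param path Path to CSV.
#' @param tol Maximum tolerated deviation of a row sum from 1 (default 1e-3).
#' @return A `founder_probs` object: list with `probs` (N x V x 8 array,
#'   dimnames mouse/marker/founder) and `map` (data frame `marker`, `chrom`,
#'   `pos_bp`).
#' @export
read_founder_probs <- function(path, tol = 1e-3) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("mouse_id", "marker", "chrom", "pos_bp", DO_FOUNDERS)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format("founder-probability file %s lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  p <- as.matrix(df[, DO_FOUNDERS])
  rs <- rowSums(p)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0) {
    stop_validation("founder probabilities at row %d (mouse %s, marker %s) sum to %.6f",
                    bad[1], df$mouse_id[bad[1]], df$marker[bad[1]], rs[bad[1]])
  }
  p <- p / rs
  mice <- unique(df$mouse_id)
  df$chrom <- as.character(df$chrom)   # chromosome names, not numbers
  map <- unique(df[, c("marker", "chrom", "pos_bp")])
  rownames(map) <- NULL
  arr <- array(NA_real_, dim = c(length(mice), nrow(map), 8),
               dimnames = list(mice, map$marker, DO_FOUNDERS))
  idx <- cbind(match(df$mouse_id, mice), match(df$marker, map$marker))
  for (f in 1:8) arr[cbind(idx, f)] <- p[, f]
  if (anyNA(arr)) {
    stop_validation("founder-probability table is not complete over mouse x marker")
  }
  as_founder_probs(arr, map)
}

#' Construct a founder-probability object from an array
#'
#' @param probs N x V x 8 array; per (mouse, marker) slices must be
#'   non-negative and sum to 1 (renormalized exactly).
#' @param map Data frame with columns `marker`, `chrom`, `pos_bp` (V rows).
#' @return A `founder_probs` object.
#' @export
as_founder_probs <- function(probs, map) {
  stopifnot(length(dim(probs)) == 3, dim(probs)[3] == 8,
            nrow(map) == dim(probs)[2],
            all(c("marker", "chrom", "pos_bp") %in% names(map)))
  if (any(probs < 0)) stop_validation("negative founder probability")
  s <- apply(probs, c(1, 2), sum)
  probs <- probs / as.vector(s)  # recycles over founder slices
  dimnames(probs)[[3]] <- DO_FOUNDERS
  structure(list(probs = probs, map = as.data.frame(map)),
            class = "founder_probs")
}

#' Write founder probabilities in the package dialect
#'
#' @param fp A `founder_probs` object.
#' @param path Output path.
#' @seealso [read_founder_probs()]
#' @export
write_founder_probs <- function(fp, path) {
  n <- dim(fp$probs)[1]; v <- dim(fp$probs)[2]
  mice <- dimnames(fp$probs)[[1]] %||% as.character(seq_len(n))
  out <- data.frame(
    mouse_id = rep(mice, each = v),
    marker = rep(fp$map$marker, times = n),
    chrom = rep(fp$map$chrom, times = n),
    pos_bp = rep(fp$map$pos_bp, times = n),
    stringsAsFactors = FALSE)
  for (f in seq_along(DO_FOUNDERS)) {
    out[[DO_FOUNDERS[f]]] <- as.vector(t(fp$probs[, , f]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# environment design
# ---------------------------------------------------------------------------

#' Construct an environment design
#'
#' Builds the N x E binary membership matrix Z over environment columns.
#' Before the intervention age each mouse belongs to exactly one generation
#' column; at and after the intervention age each mouse additionally belongs
#' to exactly one diet column.
#'
#' @param generation Generation cohort label per mouse.
#' @param diet Diet group label per mouse (may be NULL for pre-intervention
#'   designs).
#' @param mouse_id Mouse identifiers.
#' @param intervention_age Age (days) at which diets are imposed.
#' @param age Analysis age (days); diet columns are included iff
#'   `age >= intervention_age`.
#' @param diet_levels Allowed diet labels, in column order.
#' @return An `env_design` object: list with binary matrix `Z`, data frame
#'   `env_labels` (`kind`, `name`), `intervention_age`, `age`, `mouse_id`.
#' @export
env_design <- function(generation, diet = NULL, mouse_id = NULL,
                       intervention_age = 180, age = intervention_age,
                       diet_levels = DO_DIETS) {
  n <- length(generation)
  mouse_id <- as.character(mouse_id %||% seq_len(n))
  gen_levels <- sort(unique(as.character(generation)))
  Zg <- outer(as.character(generation), gen_levels, `==`) * 1
  colnames(Zg) <- paste0("gen", gen_levels)
  labels <- data.frame(kind = "generation", name = gen_levels,
                       stringsAsFactors = FALSE)
  Z <- Zg
  if (age >= intervention_age) {
    if (is.null(diet)) {
      stop_validation("diet labels required for analyses at or after the intervention age")
    }
    diet <- as.character(diet)
    unknown <- setdiff(unique(diet), diet_levels)
    if (length(unknown) > 0) {
      stop_validation("unknown diet label(s): %s", paste(unknown, collapse = ", "))
    }
    Zd <- outer(diet, diet_levels, `==`) * 1
    colnames(Zd) <- paste0("diet", diet_levels)
    keep <- colSums(Zd) > 0
    Z <- cbind(Zg, Zd[, keep, drop = FALSE])
    labels <- rbind(labels,
                    data.frame(kind = "diet", name = diet_levels[keep],
                               stringsAsFactors = FALSE))
  }
  rownames(Z) <- mouse_id
  structure(list(Z = Z, env_labels = labels,
                 intervention_age = intervention_age, age = age,
                 mouse_id = mouse_id),
            class = "env_design")
}

#' Read an environment design from a covariate table
#'
#' Expects a CSV with columns `mouse_id`, `generation`, `diet`. The returned
#' design has one binary column per generation cohort, plus one per diet
#' group when the analysis age is at or past the intervention age. In the
#' full study configuration (12 generations, 5 diets) this yields E = 17
#' environment columns post-intervention and E = 12 before.
#'
#' @inheritParams env_design
#' @param path Path to CSV.
#' @return An `env_design` object.
#' @export
read_environments <- function(path, intervention_age = 180,
                              age = intervention_age,
                              diet_levels = DO_DIETS) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mouse_id", "generation", "diet")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop_format("covariate file %s lacks column(s): %s", path,
                paste(missing_cols, collapse = ", "))
  }
  env_design(df$generation, df$diet, df$mouse_id,
             intervention_age = intervention_age, age = age,
             diet_levels = diet_levels)
}

#' Full-rank fixed-effect design from an environment design
#'
#' The mean model is an intercept plus one coefficient per environment
#' column; because generation columns (and diet columns, post-intervention)
#' each sum to one across a mouse's memberships, one reference column per
#' environment kind is dropped to keep the design full rank.
#'
#' @param design An `env_design` object, or a plain binary matrix Z (in
#'   which case the first column is treated as the reference).
#' @return Numeric model matrix with an `(Intercept)` column.
#' @export
fixed_effects_design <- function(design) {
  if (inherits(design, "env_design")) {
    Z <- design$Z
    kinds <- design$env_labels$kind
    drop_idx <- c(match("generation", kinds),
                  if ("diet" %in% kinds) match("diet", kinds))
    X <- cbind(1, Z[, -drop_idx, drop = FALSE])
  } else {
    Z <- as.matrix(design)
    X <- cbind(1, Z[, -1, drop = FALSE])
  }
  colnames(X)[1] <- "(Intercept)"
  X
}

# ---------------------------------------------------------------------------
# annotations
# ---------------------------------------------------------------------------

#' Read gene models and regulatory intervals
#'
#' Imports gene models from a GFF3 file and open-chromatin intervals from a
#' BED file, converting both to the package's internal 0-based half-open
#' coordinate convention. GFF features are 1-based closed and are shifted at
#' this boundary; BED intervals are already 0-based half-open and pass
#' through unchanged.
#'
#' @param gff Path to a GFF3 file of gene models (features with type
#'   `gene` are retained; all features are kept if none are typed `gene`).
#' @param bed Path to a BED file; the name field is interpreted as the
#'   tissue label of the regulatory element.
#' @return An `annotation_set` object: list of data frames `genes`
#'   (`chrom`, `start`, `end`, `name`, `strand`) and `regulatory`
#'   (`chrom`, `start`, `end`, `tissue`), all coordinates 0-based half-open.
#' @export
read_annotations <- function(gff, bed) {
  g <- rtracklayer::import(gff)
  if (any(g$type == "gene")) g <- g[g$type == "gene"]
  gene_name <- if (!is.null(g$Name)) g$Name else g$ID %||% rep(NA_character_, length(g))
  genes <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(g)),
    start = GenomicRanges::start(g) - 1L,   # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(g),
    name = as.character(gene_name),
    strand = as.character(GenomicRanges::strand(g)),
    stringsAsFactors = FALSE)
  b <- rtracklayer::import(bed)
  regulatory <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(b)),
    start = GenomicRanges::start(b) - 1L,
    end = GenomicRanges::end(b),
    tissue = if (!is.null(b$name)) as.character(b$name) else NA_character_,
    stringsAsFactors = FALSE)
  annotation_set(genes, regulatory)
}

#' Construct an annotation set from interval tables
#'
#' @param genes Data frame `chrom`, `start`, `end`, `name`, `strand`
#'   (0-based half-open).
#' @param regulatory Data frame `chrom`, `start`, `end`, `tissue`
#'   (0-based half-open).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(genes, regulatory) {
  check_iv <- function(df, what) {
    if (nrow(df) > 0 && any(df$start > df$end)) {
      i <- which(df$start > df$end)[1]
      stop_validation("malformed %s interval at row %d: start %d > end %d",
                      what, i, df$start[i], df$end[i])
    }
  }
  check_iv(genes, "gene"); check_iv(regulatory, "regulatory")
  structure(list(genes = genes, regulatory = regulatory),
            class = "annotation_set")
}
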