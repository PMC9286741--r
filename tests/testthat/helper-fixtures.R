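# Shared fixtures, built in code at test time.

# small DO-like population: mosaic genotypes, kinship, a two-environment
# design and its fixed-effect design matrix
make_population <- function(n = 60, n_chrom = 2, n_markers = 40, seed = 1,
                            alloc = c(1, 1)) {
  sim <- simulate_mosaics(n, n_chrom = n_chrom, n_markers = n_markers,
                          seed = seed)
  K <- compute_kinship(sim$founder_probs)
  Z <- assign_environments(n, alloc, seed = seed + 1000)
  list(sim = sim, K = K, Z = Z, X = fixed_effects_design(Z))
}

# canonical phenotype CSV with 3 mice x 5 ages
write_phen_fixture <- function(path, shuffle = FALSE) {
  df <- expand.grid(mouse_id = c("m1", "m2", "m3"),
                    age_days = c(60, 90, 120, 150, 180),
                    stringsAsFactors = FALSE)
  df$weight_g <- 20 + 0.05 * df$age_days + as.integer(factor(df$mouse_id))
  if (shuffle) df <- df[sample(nrow(df)), ]
  utils::write.csv(df[, c("mouse_id", "age_days", "weight_g")], path,
                   row.names = FALSE, quote = FALSE)
  path
}

write_gff_fixture <- function(path) {
  lines <- c(
    "##gff-version 3",
    "chr6\ttest\tgene\t101\t200\t.\t+\t.\tID=gene1;Name=Creb5like",
    "chr6\ttest\tgene\t501\t900\t.\t-\t.\tID=gene2;Name=OtherGene")
  writeLines(lines, path)
  path
}

write_bed_fixture <- function(path) {
  writeLines(c("chr6\t100\t200\tliver",
               "chr6\t700\t800\tadipose"), path)
  path
}

write_vcf_fixture <- function(path) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", DO_FOUNDERS), collapse = "\t"))
  gt <- function(...) paste(..., sep = "\t")
  rows <- c(
    # ALT private to WSB
    gt("1", "150", "v1", "A", "G", ".", "PASS", ".", "GT",
       "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "1/1"),
    # ALT in AJ, NZO, PWK
    gt("1", "250", "v2", "T", "C", ".", "PASS", ".", "GT",
       "1/1", "0/0", "0/0", "0/0", "1/1", "0/0", "1/1", "0/0"),
    # heterozygous founder call (excluded from FAP assignment)
    gt("1", "350", "v3", "G", "A", ".", "PASS", ".", "GT",
       "0/1", "0/0", "0/0", "0/0", "0/0", "0/0", "0/0", "1/1"))
  writeLines(c(hdr, rows), path)
  path
}

# linear-mixed-model fit on a small instance, reused across tests
fit_small_instance <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pop <- make_population(n = 80, n_markers = 50, seed = 5)
      vc_true <- solve_components_for_pve(c(0.4, 0.6), c(1, 1), pop$K, pop$Z)
      Y <- simulate_phenotypes(vc_true, pop$K, pop$Z, mu = 20, seed = 11)
      fit <- fit_gxemm(Y, pop$X, pop$K, pop$Z, seed = 2)
      cache <<- list(pop = pop, vc_true = vc_true, Y = Y, fit = fit)
    }
    cache
  }
})
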