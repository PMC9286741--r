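test_that("founder VCF parsing yields per-founder allele counts", {
  vcf <- write_vcf_fixture(withr::local_tempfile(fileext = ".vcf"))
  fg <- read_founder_vcf(vcf)
  expect_equal(colnames(fg$counts), DO_FOUNDERS)
  expect_equal(unname(fg$counts["v1", ]), c(0, 0, 0, 0, 0, 0, 0, 2))
  expect_equal(unname(fg$counts["v2", ]), c(2, 0, 0, 0, 2, 0, 2, 0))
  expect_equal(unname(fg$counts["v3", "AJ"]), 1)  # heterozygous call
})

test_that("dosage imputation interpolates founder probabilities linearly", {
  # two typed markers at 100 and 300 on chromosome 1
  probs <- array(0, dim = c(5, 2, 8))
  probs[1, , 8] <- 1                       # one-hot WSB at both flanks
  probs[2, , 1] <- 1                       # one-hot AJ
  probs[3, 1, 2] <- 1; probs[3, 2, 3] <- 1 # B6 -> 129 switch
  probs[4, , ] <- 1 / 8                    # uniform
  probs[5, 1, c(1, 8)] <- 0.5; probs[5, 2, c(1, 8)] <- c(0.25, 0.75)
  map <- data.frame(marker = c("t1", "t2"), chrom = "1", pos_bp = c(100, 300))
  fp <- as_founder_probs(probs, map)
  # variant at 150 (quarter of the way): WSB homozygous ALT, others REF
  counts <- rbind(c(0, 0, 0, 0, 0, 0, 0, 2),
                  c(2, 2, 2, 2, 2, 2, 2, 2),
                  c(0, 0, 0, 0, 0, 0, 0, 0))
  vmap <- data.frame(marker = c("u1", "u2", "u3"), chrom = "1",
                     pos_bp = c(150, 150, 400))
  dm <- impute_dosages(fp, counts, vmap)
  expect_equal(attr(dm, "n_skipped"), 1)   # u3 is outside the typed span
  # one-hot WSB across flanks, WSB hom ALT -> dosage 2
  expect_equal(dm$dosages[1, "u1"], 2, ignore_attr = TRUE)
  # all founders REF at u1 for AJ carrier -> 0; all-ALT variant -> 2 for all
  expect_equal(dm$dosages[2, "u1"], 0, ignore_attr = TRUE)
  expect_equal(unname(dm$dosages[, "u2"]), rep(2, 5))
  # hand-computed expectation: p(150) = 0.75 * p(100) + 0.25 * p(300)
  w <- (150 - 100) / (300 - 100)
  for (m in 1:5) {
    pm <- (1 - w) * probs[m, 1, ] + w * probs[m, 2, ]
    expect_equal(unname(dm$dosages[m, "u1"]), sum(pm * counts[1, ]),
                 tolerance = 1e-12)
  }
  # exactness: one-hot constant probabilities give the founder allele count
  expect_true(all(dm$dosages >= 0 & dm$dosages <= 2))
})

test_that("FAP assignment follows the minor-allele and tie rules", {
  # alleles A/G with A in AJ, NZO, PWK: minor side names the FAP
  alle <- c("A", "G", "G", "G", "A", "G", "A", "G")
  expect_equal(assign_fap(alle), "AJ/NZO/PWK")
  # ALT private to WSB
  expect_equal(assign_fap(c(0, 0, 0, 0, 0, 0, 0, 2)), "WSB")
  # 4/4 balanced splits: the side containing AJ is always labeled
  splits <- combn(8, 4)
  for (j in seq_len(ncol(splits))) {
    counts <- rep(0, 8); counts[splits[, j]] <- 2
    lab <- assign_fap(counts)
    expect_true(grepl("AJ", lab))
    expect_equal(length(strsplit(lab, "/")[[1]]), 4)
  }
  expect_equal(assign_fap(c(2, 2, 2, 2, 0, 0, 0, 0)), "AJ/B6/129/NOD")
  # heterozygous and monomorphic variants are excluded
  expect_true(is.na(assign_fap(c(1, 0, 0, 0, 0, 0, 0, 2))))
  expect_equal(attr(assign_fap(c(1, 0, 0, 0, 0, 0, 0, 2)), "reason"),
               "heterozygous founder")
  expect_true(is.na(assign_fap(rep(2, 8))))
  # labels use canonical founder order
  expect_equal(assign_fap(c(0, 2, 0, 0, 0, 0, 0, 2)), "B6/WSB")
})

test_that("FAP grouping partitions variants and ranks by best member LOD", {
  single <- data.frame(marker = "x", fap = "WSB", lod = 4.2, pos_bp = 10)
  g1 <- group_and_rank_faps(single)
  expect_equal(nrow(g1), 1)
  expect_equal(g1$rank, 1)
  expect_equal(g1$group_lod, 4.2)

  # max rule: group with members {3.1, 5.0} outranks {4.9}
  two <- data.frame(marker = c("a", "b", "c"),
                    fap = c("AJ", "AJ", "B6/WSB"),
                    lod = c(3.1, 5.0, 4.9),
                    pos_bp = c(1, 2, 3))
  g2 <- group_and_rank_faps(two)
  expect_equal(g2$fap[g2$rank == 1], "AJ")
  expect_equal(g2$group_lod, c(5.0, 4.9))

  # random fixture vs brute-force dictionary partition
  set.seed(14)
  faps <- sample(c("AJ", "B6", "CAST/PWK", "AJ/NOD", "129/NZO", "WSB"),
                 200, replace = TRUE)
  vb <- data.frame(marker = paste0("v", 1:200), fap = faps,
                   lod = round(runif(200, 0, 8), 3),
                   pos_bp = sample(1e6, 200))
  gb <- group_and_rank_faps(vb)
  expect_equal(nrow(gb), 6)
  expect_equal(sum(gb$n_members), 200)
  for (i in seq_len(nrow(gb))) {
    members <- vb[vb$fap == gb$fap[i], ]
    expect_equal(gb$group_lod[i], max(members$lod))
    expect_equal(gb$n_members[i], nrow(members))
    expect_equal(gb$span_start[i], min(members$pos_bp))
    expect_equal(gb$span_end[i], max(members$pos_bp))
  }
  expect_true(all(diff(gb$group_lod) <= 0))
  # no variant in two groups: membership lists are disjoint and exhaustive
  mem <- attr(gb, "members")
  expect_equal(sort(unname(unlist(mem))), sort(vb$marker))
})

test_that("variant annotation equals an all-pairs brute-force overlap check", {
  set.seed(3)
  iv <- data.frame(chrom = sample(c("1", "2"), 20, replace = TRUE),
                   start = sample(0:900, 20))
  iv$end <- iv$start + sample(10:100, 20)
  genes <- data.frame(chrom = iv$chrom[1:10], start = iv$start[1:10],
                      end = iv$end[1:10], name = paste0("g", 1:10),
                      strand = "+")
  reg <- data.frame(chrom = iv$chrom[11:20], start = iv$start[11:20],
                    end = iv$end[11:20], tissue = rep(c("liver", "muscle"), 5))
  ann <- annotation_set(genes, reg)
  v <- data.frame(chrom = sample(c("1", "2"), 50, replace = TRUE),
                  pos_bp = sample(0:1000, 50))
  av <- annotate_variants(v, ann)
  for (i in 1:50) {
    hit_g <- any(genes$chrom == v$chrom[i] &
                   genes$start <= v$pos_bp[i] & v$pos_bp[i] < genes$end)
    hit_r <- any(reg$chrom == v$chrom[i] &
                   reg$start <= v$pos_bp[i] & v$pos_bp[i] < reg$end)
    expect_equal(av$in_gene[i], hit_g)
    expect_equal(av$in_regulatory[i], hit_r)
  }
})

test_that("effect profiles recover injected effects within their uncertainty", {
  pop <- make_population(n = 250, n_markers = 30, seed = 71)
  vc0 <- solve_components_for_pve(c(0.25, 0.25), c(1, 1), pop$K, pop$Z)
  v <- 12
  g <- pop$sim$dosages$dosages[, v]
  ages <- seq(200, 400, by = 50)
  # constant 0.8 g/allele effect at every age, independent noise draws
  weight <- vapply(seq_along(ages), function(j) {
    simulate_phenotypes(vc0, pop$K, pop$Z, mu = 20 + 0.8 * g, seed = 500 + j)
  }, numeric(250))
  prof <- effect_profile(weight, ages, pop$sim$dosages, v, pop$Z, pop$K,
                         level = "founder", n_starts = 1, seed = 1)
  expect_equal(nrow(prof), length(ages))
  expect_true(all(prof$se > 0))
  expect_true(all(abs(prof$estimate - 0.8) <= 2.5 * prof$se))

  # null variant: estimates within 2 SE of zero at >= 90% of ages
  vnull <- 25
  prof0 <- effect_profile(weight - 0.8 * g, ages, pop$sim$dosages, vnull,
                          pop$Z, pop$K, level = "founder", n_starts = 1,
                          seed = 1)
  cover <- mean(abs(prof0$estimate) <= 2 * prof0$se)
  expect_gte(cover, 0.8)
})
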