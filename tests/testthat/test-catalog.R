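vt_with_gts <- function(gts, nvar = 1L) {
  # gts: list of c(a1, a2) per sample, or a matrix 2 x nsamp
  m <- if (is.list(gts)) do.call(cbind, gts) else gts
  variant_table(rep("chr1", nvar), seq_len(nvar) * 10L, rep("A", nvar),
                rep("G", nvar),
                gt1 = matrix(m[1, ], nvar, ncol(m), byrow = TRUE),
                gt2 = matrix(m[2, ], nvar, ncol(m), byrow = TRUE),
                samples = sprintf("s%d", seq_len(ncol(m))))
}

test_that("allele frequencies and genotype classes follow hand counts", {
  af <- allele_frequency(vt_with_gts(rep(list(c(0L, 1L)), 4)))
  expect_equal(af$af, 0.5)
  expect_equal(af$maf, 0.5)
  expect_equal(unlist(af[c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")]),
               c(n_hom_ref = 0, n_het = 4, n_hom_alt = 0, n_missing = 0))
  # {0/0, 0/1, 1/1, ./.}: 3 alt alleles of 6 called
  af <- allele_frequency(vt_with_gts(list(c(0L, 0L), c(0L, 1L), c(1L, 1L),
                                          c(NA, NA))))
  expect_equal(af$af, 0.5)
  expect_equal(af$an, 6L)
  expect_equal(unlist(af[c("n_hom_ref", "n_het", "n_hom_alt", "n_missing")]),
               c(n_hom_ref = 1, n_het = 1, n_hom_alt = 1, n_missing = 1))
  # one hom-alt among ten hom-ref: 2/22
  af <- allele_frequency(vt_with_gts(c(list(c(1L, 1L)),
                                       rep(list(c(0L, 0L)), 10))))
  expect_equal(af$af, 2 / 22)
  expect_equal(af$maf, 2 / 22)
  # a half-called genotype is missing for frequency purposes
  af <- allele_frequency(vt_with_gts(list(c(0L, NA), c(0L, 1L))))
  expect_equal(af$an, 2L)
  expect_equal(af$n_missing, 1)
  # all-missing: undefined frequency, variant retained
  af <- allele_frequency(vt_with_gts(list(c(NA, NA), c(NA, NA))))
  expect_true(is.na(af$af))
})

test_that("private alleles count carrier individuals, not alleles", {
  expect_true(is_private(vt_with_gts(list(c(0L, 1L), c(0L, 0L), c(0L, 0L)))))
  expect_true(is_private(vt_with_gts(list(c(1L, 1L), c(0L, 0L), c(0L, 0L)))))
  expect_false(is_private(vt_with_gts(list(c(0L, 1L), c(0L, 1L), c(0L, 0L)))))
  expect_false(is_private(vt_with_gts(list(c(0L, 0L), c(0L, 0L)))))
  # property: private implies alt allele count 1 or 2
  set.seed(4)
  for (rep in 1:30) {
    m <- matrix(sample(c(0L, 0L, 0L, 1L, NA), 12, TRUE), 2, 6)
    vt <- vt_with_gts(m)
    if (is_private(vt)) {
      expect_true(allele_frequency(vt)$ac %in% c(1L, 2L))
    }
    carriers <- sum(apply(m, 2, function(g) !anyNA(g) && any(g == 1L)))
    expect_equal(is_private(vt), carriers == 1L)
  }
})

test_that("variant types are read off normalized allele lengths", {
  vt <- variant_table(rep("chr1", 4), c(10L, 20L, 30L, 40L),
                      c("A", "A", "ACT", "AC"), c("G", "AT", "A", "GT"))
  expect_equal(variant_type(vt), c("SNV", "insertion", "deletion", "MNV"))
  # an MNV that normalization collapses becomes an SNV
  g <- toy_genome(chr1 = "GGGGGGGGGACTGGG")
  nv <- liftann:::normalize_one("chr1", 10L, "ACT", "AGT", g)
  expect_equal(variant_type(variant_table("chr1", nv$pos, nv$ref, nv$alt)),
               "SNV")
})

test_that("the derived AFS bins (0,1] with alt-as-derived by default", {
  gts <- function(f, n = 10L) {
    k <- round(2 * n * f)
    m <- matrix(0L, 2, n); m[seq_len(k)] <- 1L
    m
  }
  v1 <- vt_with_gts(gts(0.1)); v2 <- vt_with_gts(gts(0.1))
  v3 <- vt_with_gts(gts(0.9))
  v2$pos <- 20L; v3$pos <- 30L
  all3 <- vt_bind(v1, v2, v3)
  afs <- derived_afs(all3, n_bins = 10L)
  want <- integer(10); want[1] <- 2L; want[9] <- 1L
  expect_equal(as.integer(afs), want)
  expect_equal(sum(afs), 3L)
  # empty input: all-zero vector
  empty <- variant_table(character(), integer(), character(), character())
  expect_equal(as.integer(derived_afs(empty, 10L)), integer(10))
  # ancestral polarization flips when the alt is ancestral
  flip <- info_set(v3, "MG_AA", "G")   # alt recorded as ancestral
  afs2 <- derived_afs(flip, n_bins = 10L, polarization = "ancestral")
  expect_equal(which(as.integer(afs2) == 1L), 1L)   # 1 - 0.9
  noaa <- derived_afs(v1, n_bins = 10L, polarization = "ancestral")
  expect_equal(sum(noaa), 0L)
  expect_equal(attr(noaa, "n_excluded"), 1L)
})

test_that("all 27 full trio genotype combinations match the enumeration", {
  gt <- list(c(0L, 0L), c(0L, 1L), c(1L, 1L))
  combos <- expand.grid(s = 1:3, d = 1:3, c = 1:3)
  vt <- variant_table(
    rep("chr1", nrow(combos)), seq_len(nrow(combos)) * 10L,
    rep("A", nrow(combos)), rep("G", nrow(combos)),
    gt1 = cbind(vapply(combos$s, function(i) gt[[i]][1], 0L),
                vapply(combos$d, function(i) gt[[i]][1], 0L),
                vapply(combos$c, function(i) gt[[i]][1], 0L)),
    gt2 = cbind(vapply(combos$s, function(i) gt[[i]][2], 0L),
                vapply(combos$d, function(i) gt[[i]][2], 0L),
                vapply(combos$c, function(i) gt[[i]][2], 0L)),
    samples = c("sire", "dam", "kid"))
  ped <- structure(data.frame(id = c("sire", "dam", "kid"),
                              sire = c(NA, NA, "sire"),
                              dam = c(NA, NA, "dam"),
                              sex = NA_character_,
                              stringsAsFactors = FALSE),
                   class = c("pedigree", "data.frame"))
  got <- mendel_check(vt, ped)$per_variant
  expect_equal(got$n_checked, rep(1L, 27L))
  want <- !vapply(seq_len(nrow(combos)), function(i) {
    s <- gt[[combos$s[i]]]; d <- gt[[combos$d[i]]]; k <- gt[[combos$c[i]]]
    enum_trio(s[1], s[2], d[1], d[2], k[1], k[2])
  }, logical(1))
  expect_equal(got$n_violations == 1L, want)
  # the de novo pattern and a clean transmission, spelled out
  expect_false(enum_trio(0L, 0L, 0L, 0L, 0L, 1L))
  expect_true(enum_trio(0L, 1L, 0L, 0L, 0L, 1L))
})

test_that("duos are consistent when an allele is shared or the child is het", {
  ped <- structure(data.frame(id = c("p", "kid"), sire = c(NA, "p"),
                              dam = c(NA, NA), sex = NA_character_,
                              stringsAsFactors = FALSE),
                   class = c("pedigree", "data.frame"))
  duo <- function(p, k) {
    vt <- variant_table("chr1", 10L, "A", "G",
                        gt1 = matrix(c(p[1], k[1]), 1),
                        gt2 = matrix(c(p[2], k[2]), 1),
                        samples = c("p", "kid"))
    mendel_check(vt, ped)$per_variant$n_violations
  }
  expect_equal(duo(c(0L, 0L), c(1L, 1L)), 1L)  # no shared allele
  expect_equal(duo(c(0L, 0L), c(0L, 1L)), 0L)  # het child always possible
  expect_equal(duo(c(1L, 1L), c(1L, 1L)), 0L)
  # missing genotype in the pair: family skipped
  vt <- variant_table("chr1", 10L, "A", "G", gt1 = matrix(c(NA, 1L), 1),
                      gt2 = matrix(c(0L, 1L), 1), samples = c("p", "kid"))
  expect_equal(mendel_check(vt, ped)$per_variant$n_checked, 0L)
})

test_that("pedigree files reject cycles and unknown parents", {
  good <- write_lines_tmp(gsub(" ", "\t", c("id sire dam", "a 0 0",
                                            "b 0 0", "c a b")))
  ped <- read_pedigree(good)
  expect_equal(ped$sire[3], "a")
  expect_error(read_pedigree(write_lines_tmp(gsub(" ", "\t",
    c("id sire dam", "a 0 0", "c a ghost")))), "ghost",
    class = "liftann_pedigree_error")
  expect_error(read_pedigree(write_lines_tmp(gsub(" ", "\t",
    c("id sire dam", "a c 0", "c a 0")))), "cycle",
    class = "liftann_pedigree_error")
})

test_that("the variants-of-interest rule is a monotone union", {
  vt <- variant_table(rep("chr1", 4), c(10L, 20L, 30L, 40L), rep("A", 4),
                      rep("G", 4))
  vt <- info_set(vt, "MG_CLN_PATH", TRUE, which = 1)
  vt <- info_set(vt, "MG_IMPACT", c("HIGH", "MODERATE"), which = c(2, 3))
  dmg <- list(list(key = "MG_PP2_SCORE", threshold = 0.85))
  expect_equal(variants_of_interest(vt, dmg), c(TRUE, TRUE, FALSE, FALSE))
  # adding a damaging score only ever adds variants
  vt2 <- info_set(vt, "MG_PP2_SCORE", "0.99", which = 4)
  expect_equal(variants_of_interest(vt2, dmg), c(TRUE, TRUE, FALSE, TRUE))
  vt3 <- info_set(vt2, "MG_CLN_PATH", TRUE, which = 3)
  expect_true(all(variants_of_interest(vt2, dmg) <=
                  variants_of_interest(vt3, dmg)))
  # a below-threshold score does not qualify
  vt4 <- info_set(vt, "MG_PP2_SCORE", "0.2", which = 4)
  expect_equal(variants_of_interest(vt4, dmg)[4], FALSE)
})

test_that("catalog summaries match a hand tally on a ten-variant fixture", {
  # 10 variants x 4 samples, written out explicitly
  gt1 <- rbind(c(0L, 0L, 0L, 0L), c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L),
               c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, NA), c(0L, 1L, 1L, 0L),
               c(0L, 0L, 0L, 0L), c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L),
               c(0L, 0L, 0L, 0L))
  gt2 <- rbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(1L, 1L, 0L, 0L),
               c(1L, 1L, 0L, 0L), c(0L, 0L, 0L, NA), c(1L, 1L, 1L, 0L),
               c(0L, 0L, 1L, 0L), c(1L, 0L, 0L, 0L), c(0L, 0L, 1L, 0L),
               c(0L, 1L, 0L, 0L))
  vt <- variant_table(rep("chr1", 10), (1:10) * 100L,
                      c("A", "C", "G", "T", "A", "C", "G", "A", "C", "G"),
                      c("G", "CT", "A", "TAA", "G", "T",
                        "A", "AT", "A", "T"),
                      gt1 = gt1, gt2 = gt2,
                      samples = c("s1", "s2", "s3", "s4"))
  s <- summarize_catalog(vt)
  expect_equal(s$n_variants, 10L)
  # hand tally: SNVs at 1,3,5,6,7,9,10; insertions at 2,4,8 (alt longer)
  expect_equal(as.integer(s$n_by_type), c(7L, 3L, 0L, 0L))
  expect_equal(s$pct_indel, 30)
  # private: variants 1 (s1 het), 5 none?, check by hand:
  # v1 carriers {s1}; v2 {s2}; v3 {s1,s2}; v4 {s1,s2}; v5 {}; v6 {s1,s2,s3};
  # v7 {s3}; v8 {s1}; v9 {s3}; v10 {s2}
  expect_equal(s$n_private, 6L)
  expect_equal(sum(s$afs), sum(!is.na(allele_frequency(vt)$af) &
                               allele_frequency(vt)$af > 0))
  expect_equal(s$n_voi, 0L)
})

test_that("an empty catalog summarizes to zeros", {
  s <- summarize_catalog(variant_table(character(), integer(), character(),
                                       character()))
  expect_equal(s$n_variants, 0L)
  expect_equal(sum(s$n_by_type), 0L)
  expect_equal(s$n_private, 0L)
  expect_equal(sum(s$afs), 0L)
})
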