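test_that("synonymous-codon permutation conserves protein and codon pool", {
  # singleton families: nothing can move
  expect_identical(permuteSynonymousCodons(c(g1 = "ATGTTATAA"), seed = 1),
                   c(g1 = "ATGTTATAA"))

  # two Leu codons across genes: the multiset {CTT, TTA} is conserved
  got <- replicate(20, permuteSynonymousCodons(
    c(g1 = "ATGCTTTAA", g2 = "ATGTTATAA"), seed = NULL))
  leu <- apply(got, 2, function(o) sort(c(substr(o[1], 4, 6),
                                          substr(o[2], 4, 6))))
  expect_true(all(apply(leu, 2, identical, y = c("CTT", "TTA"))))
  expect_true(any(got[1, ] != "ATGCTTTAA"))  # swaps do happen

  # non-triplet ORFs are skipped with a warning
  expect_warning(out <- permuteSynonymousCodons(c(a = "ATGT"), seed = 1),
                 "divisible")
  expect_identical(out, c(a = "ATGT"))

  # genome-scale conservation laws, exact
  g <- synth_genome(nGenes = 30, seed = 5)
  orfs <- vapply(g$models, function(m)
    arsiscan:::region_seq(as.character(g$genome[[m@chrom]]), m@cds,
                          m@strand), "")
  rnd <- suppressMessages(permuteSynonymousCodons(orfs, seed = 77))
  translate <- function(x) suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAStringSet(x),
                          if.fuzzy.codon = "solve")))
  expect_identical(translate(rnd), translate(orfs))
  codon_count <- function(x) sort(table(unlist(lapply(x, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))))
  expect_identical(codon_count(rnd), codon_count(orfs))
  expect_true(sum(rnd != orfs) > 20)  # and it is not the identity
})

test_that("intron permutation fixes consensus positions exactly", {
  set.seed(8)
  mid <- rand_dna(40)
  gap <- rand_dna(20)
  intron <- paste0("GTATGT", mid, "TACTAAC", gap, "TAG")
  n <- nchar(intron)
  r <- permuteIntron(intron, seed = 3)
  expect_identical(nchar(r), n)
  expect_identical(substr(r, 1, 6), "GTATGT")
  expect_identical(substring(r, n - 2), "TAG")
  bs_at <- 6L + 40L + 1L
  expect_identical(substr(r, bs_at, bs_at + 6L), "TACTAAC")
  # exact composition (hence GC) conservation
  expect_identical(sort(strsplit(r, "")[[1]]), sort(strsplit(intron, "")[[1]]))
  expect_false(identical(r, intron))

  # all-A free positions: permutation is invisible
  quiet <- paste0("GTATGT", strrep("A", 30), "TACTAAC", strrep("A", 20), "TAG")
  expect_identical(permuteIntron(quiet, seed = 1), quiet)

  expect_warning(permuteIntron("GTATGTAG", seed = 1), "too short")
})

test_that("UTR cyclic shifts preserve composition and 5' context", {
  expect_identical(arsiscan:::rotate_right("ACGTAC", 2L), "ACACGT")

  set.seed(12)
  u3 <- rand_dna(80)
  r3 <- cyclicShiftUtr(u3, "three", seed = 4)
  expect_identical(nchar(r3), 80L)
  expect_identical(sort(strsplit(r3, "")[[1]]), sort(strsplit(u3, "")[[1]]))
  # the result is a genuine nontrivial rotation
  rots <- vapply(1:79, function(k) arsiscan:::rotate_right(u3, k), "")
  expect_true(r3 %in% rots)

  u5 <- paste0(rand_dna(50), "CCGGTT")
  r5 <- cyclicShiftUtr(u5, "five", contextLen = 6L, seed = 4)
  expect_identical(substring(r5, 51), "CCGGTT")  # ATG context fixed
  expect_identical(sort(strsplit(r5, "")[[1]]), sort(strsplit(u5, "")[[1]]))
  expect_false(identical(substr(r5, 1, 50), substr(u5, 1, 50)))

  expect_identical(cyclicShiftUtr("A", "three", seed = 1), "A")
})

extract_all <- function(genome, models) {
  lapply(models, function(m) regionSeqs(extractRegions(genome, m)))
}

test_that("randomization schemes are isolated, seeded and commutative", {
  g <- synth_genome(nGenes = 30, seed = 5)
  before <- extract_all(g$genome, g$models)

  rc <- suppressMessages(
    randomizeGenome(g$genome, g$models, scheme = "codons", seed = 13))
  after <- extract_all(rc, g$models)
  for (gid in names(before)) {
    b <- before[[gid]]; a <- after[[gid]]
    ik <- grep("intron|utr|flank", names(b))
    expect_identical(a[ik], b[ik])  # codons-only leaves the rest untouched
  }
  expect_true(sum(vapply(names(before), function(gid)
    before[[gid]][["orf"]] != after[[gid]][["orf"]], logical(1))) > 20)

  # same seed, same genome
  rc2 <- suppressMessages(
    randomizeGenome(g$genome, g$models, scheme = "codons", seed = 13))
  expect_identical(as.character(rc), as.character(rc2))

  # schemes act on disjoint regions and commute
  all1 <- suppressMessages(randomizeGenome(g$genome, g$models,
                                           scheme = "all", seed = 29))
  step <- g$genome
  for (s in c("utrs", "codons", "introns")) {
    step <- suppressMessages(randomizeGenome(step, g$models, scheme = s,
                                             seed = 29))
  }
  expect_identical(as.character(all1), as.character(step))
})

test_that("z-scores standardize against the ensemble correctly", {
  ens <- methods::new("NullEnsemble", scheme = "codons", R = 4L,
                      seed = 1L, stats = list(c(1, 10), c(2, 10),
                                              c(3, 10), c(4, 10)))
  z <- zScore(c(2.5, 10), ens)
  expect_equal(z[1], 0)                      # real at the null mean
  expect_true(is.na(z[2]))                   # sd 0 -> flagged, not Inf
  expect_identical(attr(z, "undefined"), 2L)
  sdv <- sd(1:4)
  expect_equal(zScore(c(2.5 + 2 * sdv, 10), ens)[1], 2)
})

test_that("ensemble replicates are reproducible and R >= 2 is enforced", {
  g <- synth_genome(nGenes = 30, seed = 5)
  stat <- function(gen, mods) {
    sc <- scoreRegions(gen, mods, "orf")
    mean(sc$arsi)
  }
  e1 <- suppressMessages(nullEnsemble(g$genome, g$models, stat, R = 3,
                                      seed = 6))
  e2 <- suppressMessages(nullEnsemble(g$genome, g$models, stat, R = 3,
                                      seed = 6))
  expect_equal(e1@stats, e2@stats)
  expect_error(nullEnsemble(g$genome, g$models, stat, R = 1, seed = 1),
               "R must be")
})

test_that("the paired signed-rank test behaves at its edge cases", {
  x <- rnorm(30)
  expect_message(r0 <- pairedRealVsRandomTest(x, x), "p = 1")
  expect_equal(r0$p.value, 1)

  set.seed(9)
  base <- rnorm(50)
  r1 <- pairedRealVsRandomTest(base + 1, base)
  expect_lt(r1$p.value, 1e-8)
  expect_equal(r1$median_real - r1$median_random, 1)

  # antisymmetric differences sit at the null center
  d <- rep(c(1, -1, 2, -2, 3, -3), 5)
  r2 <- pairedRealVsRandomTest(base[1:30] + d, base[1:30])
  expect_gt(r2$p.value, 0.9)
})
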