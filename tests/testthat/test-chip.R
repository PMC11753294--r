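# Consensus peaks, differential region calling (both modes), enhancer
# filtering and peak-to-gene annotation.

test_that("consensus of identical replicates returns the input intervals", {
  peaks <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 700L))
  out <- consensus_peaks(list(peaks, peaks))
  expect_equal(out[, c("chrom", "start", "end")], peaks,
               ignore_attr = TRUE)
  expect_equal(out$n_replicates, c(2L, 2L))
})

test_that("peaks in a single replicate are excluded at min_replicates 2", {
  r1 <- data.frame(chrom = "chr1", start = c(100L, 500L), end = c(200L, 700L))
  r2 <- data.frame(chrom = "chr1", start = 120L, end = 210L)
  out <- consensus_peaks(list(r1, r2), min_replicates = 2)
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100L)
  expect_equal(out$end, 210L)   # union of the contributing intervals
  expect_error(consensus_peaks(list(r1), min_replicates = 2), "exceeds")
})

test_that("consensus equals the exhaustive pairwise-overlap merge oracle", {
  set.seed(31)
  for (rep_i in 1:5) {
    reps <- lapply(1:3, function(i) {
      s <- sort(sample(0:500, 8)) * 10L
      data.frame(chrom = sample(c("c1", "c2"), 8, TRUE), start = s,
                 end = s + sample(50:400, 8))
    })
    for (mr in 1:3) {
      got <- consensus_peaks(reps, min_replicates = mr)
      want <- oracle_consensus(reps, min_replicates = mr)
      expect_equal(got[, c("chrom", "start", "end")], want,
                   ignore_attr = TRUE)
    }
  }
})

test_that("presence/absence regions behave at the extremes and swap cleanly", {
  a <- data.frame(chrom = "chr1", start = c(0L, 1000L), end = c(100L, 1100L),
                  name = c("a1", "a2"))
  expect_equal(nrow(differential_regions_presence(a, a)), 0)
  b <- data.frame(chrom = "chr1", start = 5000L, end = 5100L, name = "b1")
  der <- differential_regions_presence(a, b)
  expect_equal(sum(der$direction == 1), 2)   # all case peaks gained
  expect_equal(sum(der$direction == -1), 1)  # all control peaks lost
  swapped <- differential_regions_presence(b, a)
  expect_setequal(der$name[der$direction == 1], swapped$name[swapped$direction == -1])
  expect_setequal(der$name[der$direction == -1], swapped$name[swapped$direction == 1])
})

test_that("jittered shared peaks are not called; planted uniques are", {
  set.seed(33)
  shared <- data.frame(chrom = "chr1", start = seq(1000L, 20000L, 2000L))
  shared$end <- shared$start + 800L
  jig <- function(df, j) {
    df$start <- df$start + sample(-50:50, nrow(df), TRUE)
    df$end <- df$end + sample(-50:50, nrow(df), TRUE)
    df
  }
  unique_case <- data.frame(chrom = "chr1", start = 50000L, end = 50600L)
  unique_ctrl <- data.frame(chrom = "chr1", start = 70000L, end = 70500L)
  case <- rbind(jig(shared), unique_case)
  ctrl <- rbind(jig(shared), unique_ctrl)
  case$name <- sprintf("c%d", seq_len(nrow(case)))
  ctrl$name <- sprintf("k%d", seq_len(nrow(ctrl)))
  der <- differential_regions_presence(case, ctrl)
  expect_equal(der$start[der$direction == 1], 50000L)
  expect_equal(der$start[der$direction == -1], 70000L)
})

test_that("count-based regions: no signal means no calls, order irrelevant", {
  m <- matrix(rep(rpois(20, 200), 8), ncol = 8,
              dimnames = list(sprintf("peak%02d", 1:20), sprintf("s%d", 1:8)))
  cm <- make_cm(m, group = rep(c("case", "control"), each = 4))
  expect_equal(nrow(differential_regions_counts(cm)), 0)

  set.seed(35)
  m2 <- matrix(rnbinom(30 * 8, mu = 150, size = 20), ncol = 8,
               dimnames = list(sprintf("peak%02d", 1:30), sprintf("s%d", 1:8)))
  m2[1:5, 1:4] <- m2[1:5, 1:4] * 4L
  cm2 <- make_cm(m2, group = rep(c("case", "control"), each = 4))
  d1 <- differential_regions_counts(cm2)
  perm <- sample(nrow(m2))
  cm3 <- make_cm(m2[perm, ], group = rep(c("case", "control"), each = 4))
  d2 <- differential_regions_counts(cm3)
  expect_setequal(d1$peak, d2$peak)
})

test_that("planted fourfold gains are recovered at FDR 0.05", {
  set.seed(37)
  n_peaks <- 200
  mu0 <- exp(runif(n_peaks, log(80), log(300)))
  gain <- seq_len(40)
  mu <- cbind(matrix(mu0, n_peaks, 4), matrix(mu0, n_peaks, 4))
  mu[gain, 1:4] <- mu[gain, 1:4] * 4
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.05), n_peaks,
              dimnames = list(sprintf("peak%03d", seq_len(n_peaks)),
                              sprintf("s%d", 1:8)))
  cm <- make_cm(y, group = rep(c("case", "control"), each = 4))
  der <- differential_regions_counts(cm, fdr = 0.05)
  recovered <- mean(sprintf("peak%03d", gain) %in% der$peak[der$direction == 1])
  expect_gte(recovered, 0.8)
})

test_that("enhancer filtering applies both quartile rules and the gene cap", {
  # all scores equal: nothing removed by score; <= 5 genes retained
  enh <- data.frame(chrom = "chr1", start = (0:3) * 1000L,
                    end = (0:3) * 1000L + 500L,
                    enhancer_id = paste0("e", 1:4), score = 1)
  assoc <- data.frame(enhancer_id = rep(paste0("e", 1:4), times = c(2, 5, 6, 1)),
                      gene = sprintf("g%02d", 1:14), score = 5)
  db <- filter_enhancer_associations(enhancer_db(enh, assoc))
  expect_setequal(db$enhancers$enhancer_id, c("e1", "e2", "e4"))  # e3 has 6 genes
  expect_false("e3" %in% db$associations$enhancer_id)

  # random db vs direct quantile-filter oracle
  set.seed(41)
  n_e <- 30
  enh <- data.frame(chrom = "chr1", start = (seq_len(n_e) - 1L) * 2000L,
                    end = (seq_len(n_e) - 1L) * 2000L + 500L,
                    enhancer_id = sprintf("e%02d", seq_len(n_e)),
                    score = round(runif(n_e), 3))
  assoc <- do.call(rbind, lapply(seq_len(n_e), function(i) {
    k <- sample(1:7, 1)
    data.frame(enhancer_id = enh$enhancer_id[i],
               gene = sprintf("g%03d", sample(1:60, k)),
               score = round(runif(k, 0, 20), 2))
  }))
  got <- filter_enhancer_associations(enhancer_db(enh, assoc))
  q1e <- quantile(enh$score, 0.25, names = FALSE)
  q1a <- quantile(assoc$score, 0.25, names = FALSE)
  keep_e <- enh$enhancer_id[enh$score >= q1e]
  keep_a <- assoc[assoc$score >= q1a & assoc$enhancer_id %in% keep_e, ]
  over <- names(which(table(keep_a$enhancer_id) > 5))
  keep_e <- setdiff(keep_e, over)
  keep_a <- keep_a[!keep_a$enhancer_id %in% over, ]
  expect_setequal(got$enhancers$enhancer_id, keep_e)
  expect_equal(nrow(got$associations), nrow(keep_a))
})

test_that("peak annotation reproduces the hand-computed toy-genome table", {
  toy <- toy_genome()
  ders <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr1", "chr1", "chr3", "chr2"),
    start = c(9900L, 30000L, 50000L, 80500L, 75000L, 102000L, 2900L, 2100L),
    end   = c(10100L, 30500L, 50200L, 80600L, 75100L, 102500L, 3101L, 2200L),
    name = sprintf("p%d", 1:8),
    direction = c(1, 1, 1, 1, -1, 1, 1, -1)
  )
  out <- annotate_peaks(ders, toy$annotation, toy$db)
  # hand-computed expectation:
  # p1 overlaps gA promoter window            -> promoter gA, +1
  # p2 intergenic, no enhancer                -> dropped
  # p3 inside gB body, 10 kb from its TSS     -> discarded (genic non-promoter)
  # p4 intergenic on e1                       -> enhancer gB and gC, +1
  # p5 intergenic on e2                       -> enhancer gA, -1
  # p6 overlaps gC promoter window (and body) -> promoter gC, +1
  # p7 equidistant (1900 bp) from gE and gF   -> tie, lexicographic: gE
  # p8 in gD promoter window on chr2          -> promoter gD, -1
  want <- data.frame(
    gene = c("gA", "gA", "gB", "gC", "gC", "gD", "gE"),
    direction = c(1, -1, 1, 1, 1, -1, 1),
    element = c("promoter", "enhancer", "enhancer", "enhancer", "promoter",
                "promoter", "promoter"),
    peak = c("p1", "p5", "p4", "p4", "p6", "p8", "p7"),
    stringsAsFactors = FALSE
  )
  want <- want[order(want$gene, want$peak), ]
  expect_equal(as.data.frame(out), want, ignore_attr = TRUE)
})

test_that("annotation is independent of peak order and warns on unknown chroms", {
  toy <- toy_genome()
  ders <- data.frame(chrom = c("chr1", "chr9"), start = c(9900L, 100L),
                     end = c(10100L, 200L), name = c("p1", "p2"),
                     direction = c(1, 1))
  expect_warning(out <- annotate_peaks(ders, toy$annotation, toy$db),
                 "skipped")
  expect_equal(out$gene, "gA")
  ders_rev <- ders[2:1, ]
  expect_warning(out_rev <- annotate_peaks(ders_rev, toy$annotation, toy$db))
  expect_equal(as.data.frame(out), as.data.frame(out_rev))
})
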