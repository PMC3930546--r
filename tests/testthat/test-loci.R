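mk_assoc <- function(pos, p, chr = "1") {
  list(assoc = data.frame(predictor_id = sprintf("s%02d", seq_along(pos)),
                          p = p, r = -p, stringsAsFactors = FALSE),
       snp_info = data.frame(snp_id = sprintf("s%02d", seq_along(pos)),
                             chr = chr, pos = pos,
                             stringsAsFactors = FALSE))
}

test_that("two strong SNPs within the window form one locus", {
  x <- mk_assoc(pos = c(1e6, 1e6 + 5e4), p = c(1e-5, 1e-5))
  ls <- define_loci(x$assoc, x$snp_info)
  expect_equal(nrow(ls$loci), 1)
  expect_equal(ls$loci$n_members, 2)
  expect_equal(ls$loci$seed_snp, "s01")
  validate_loci(ls, x$assoc, x$snp_info)
})

test_that("one strong SNP qualifies only with three additional weak SNPs", {
  pos <- c(1e6, 1e6 + 2e4, 1e6 + 4e4, 1e6 + 9e4)
  x <- mk_assoc(pos = pos, p = c(1e-5, 5e-4, 5e-4, 5e-4))
  ls <- define_loci(x$assoc, x$snp_info)
  expect_equal(nrow(ls$loci), 1)
  expect_equal(ls$loci$n_members, 4)
  x2 <- mk_assoc(pos = pos[1:3], p = c(1e-5, 5e-4, 5e-4))
  expect_equal(nrow(define_loci(x2$assoc, x2$snp_info)$loci), 0)
})

test_that("window boundaries are closed and chromosome-restricted", {
  x <- mk_assoc(pos = c(1e6, 1e6 + 1e5, 1e6 + 1e5 + 1),
                p = c(1e-5, 1e-5, 1e-6))
  # the strongest SNP seeds first and picks up only the SNP exactly 1e5 away
  ls <- define_loci(x$assoc, x$snp_info)
  expect_equal(ls$loci$seed_snp[1], "s03")
  expect_equal(sort(ls$members$snp_id[ls$members$locus_id == 1]),
               c("s02", "s03"))
  # same positions on different chromosomes never cluster
  y <- mk_assoc(pos = c(1e6, 1e6 + 5e4), p = c(1e-5, 1e-5),
                chr = c("1", "2"))
  expect_equal(nrow(define_loci(y$assoc, y$snp_info)$loci), 0)
})

test_that("locus construction matches the brute-force oracle on random panels", {
  for (seed in 1:50) {
    inst <- random_locus_instance(n_snps = 300, seed = seed)
    got <- define_loci(inst$assoc, inst$snp_info)
    want <- oracle_define_loci(inst$assoc, inst$snp_info)
    expect_equal(nrow(got$loci), length(want))
    for (i in seq_along(want)) {
      expect_equal(got$loci$seed_snp[i], want[[i]]$seed)
      expect_equal(sort(got$members$snp_id[got$members$locus_id == i]),
                   want[[i]]$members)
    }
    validate_loci(got, inst$assoc, inst$snp_info)
  }
})

test_that("locus output is invariant to association-table row order", {
  inst <- random_locus_instance(n_snps = 400, seed = 99)
  a <- define_loci(inst$assoc, inst$snp_info)
  set.seed(1)
  perm <- sample(nrow(inst$assoc))
  b <- define_loci(inst$assoc[perm, ], inst$snp_info)
  expect_equal(a$loci, b$loci)
  expect_equal(a$members, b$members)
})

test_that("nearest-gene annotation handles containment, ties and bare chromosomes", {
  loci <- data.frame(locus_id = 1:3, seed_snp = c("a", "b", "c"),
                     chr = c("1", "1", "2"),
                     seed_pos = c(500, 1500, 100),
                     stringsAsFactors = FALSE)
  genes <- data.frame(gene_symbol = c("ZZZ", "AAA", "MMM"),
                      chr = c("1", "1", "1"),
                      start = c(400, 2500, 2500), end = c(600, 3500, 3500),
                      stringsAsFactors = FALSE)
  ann <- suppressMessages(annotate_nearest_gene(loci, genes))
  expect_equal(ann$nearby_gene[1], "ZZZ")
  expect_equal(ann$gene_distance[1], 0)
  expect_equal(ann$region[1], "within")
  # seed 2: ZZZ at distance 900, AAA/MMM tied at 1000 -> ZZZ nearest
  expect_equal(ann$nearby_gene[2], "ZZZ")
  expect_equal(ann$region[2], "downstream")
  # no gene on chromosome 2
  expect_true(is.na(ann$nearby_gene[3]))
  # exact tie between two genes resolves lexicographically
  tie <- data.frame(locus_id = 1, seed_snp = "t", chr = "1",
                    seed_pos = 2000, stringsAsFactors = FALSE)
  tg <- data.frame(gene_symbol = c("BBB", "AAB"), chr = "1",
                   start = c(2500, 1000), end = c(3000, 1500),
                   stringsAsFactors = FALSE)
  expect_message(ann2 <- annotate_nearest_gene(tie, tg), "tie")
  expect_equal(ann2$nearby_gene, "AAB")
})

test_that("nearest-gene choice matches an all-pairs distance oracle", {
  set.seed(111)
  genes <- data.frame(gene_symbol = sprintf("G%03d", 1:40),
                      chr = as.character(sample(1:3, 40, replace = TRUE)),
                      start = sample.int(1e6, 40), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(5e4, 40)
  for (i in 1:200) {
    chr <- as.character(sample(1:3, 1))
    pos <- sample.int(1.1e6, 1)
    loci <- data.frame(locus_id = 1, seed_snp = "x", chr = chr,
                       seed_pos = pos, stringsAsFactors = FALSE)
    ann <- suppressMessages(annotate_nearest_gene(loci, genes))
    g <- genes[genes$chr == chr, ]
    d <- pmax(g$start - pos, pos - g$end, 0)
    expect_equal(ann$gene_distance, min(d))
    expect_true(ann$nearby_gene %in% g$gene_symbol[d == min(d)])
  }
})

test_that("shared loci between drugs are found by gene symbol and overlap", {
  a <- data.frame(seed_snp = c("r1", "r2"), nearby_gene = c("X", "Y"),
                  chr = c("1", "2"), window_start = c(1, 100),
                  window_end = c(50, 200), stringsAsFactors = FALSE)
  b <- data.frame(seed_snp = c("r3", "r4"), nearby_gene = c("Y", "Z"),
                  chr = c("2", "3"), window_start = c(150, 5),
                  window_end = c(260, 9), stringsAsFactors = FALSE)
  got <- common_loci(a, b)
  expect_equal(got$shared_genes, "Y")
  expect_equal(nrow(got$overlaps), 1)
  expect_equal(got$overlaps$a, "r2")
  # disjoint and identical inputs
  expect_equal(common_loci(a, data.frame(nearby_gene = "Q"))$shared_genes,
               character(0))
  expect_equal(common_loci(a, a)$shared_genes, c("X", "Y"))
})
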