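test_that("coding-sequence QC applies the start/stop/frame rules", {
  expect_equal(qc_gene(c(a = "ATGAAATGA", b = "ATGAAATGA")), "PASS")
  expect_equal(qc_gene(c(a = "ATGTGAAAA", b = "ATGAAAAAA")),
               "PREMATURE_STOP")
  expect_equal(qc_gene(c(a = "ATGAA", b = "ATGAA")),
               "LENGTH_NOT_MULTIPLE_OF_3")
  expect_equal(qc_gene(c(a = "TTGAAAAAA", b = "TTGAAAAAA")), "NO_ATG")
  expect_error(qc_gene(c(a = "ATGAAA", b = "ATGAAAAAA")), "unequal")
})

test_that("NG86 site counts per codon sum to three", {
  tb <- mitoscan:::ng86_tables()
  sense <- !names(tb$syn_sites) %in% c("TAA", "TAG", "TGA")
  s <- tb$syn_sites[sense]
  expect_true(all(s >= 0 & s <= 3))
  # nonsynonymous sites are defined as 3 - synonymous, so the invariant
  # is that syn counts match an independent recount from the code table
  aa <- Biostrings::GENETIC_CODE
  nt <- c("A", "C", "G", "T")
  for (codon in sample(names(s), 12)) {
    cnt <- 0
    for (pos in 1:3) for (b in setdiff(nt, substr(codon, pos, pos))) {
      alt <- codon
      substr(alt, pos, pos) <- b
      if (!alt %in% c("TAA", "TAG", "TGA") && aa[[alt]] == aa[[codon]])
        cnt <- cnt + 1
    }
    expect_equal(unname(s[codon]), cnt / 3, label = codon)
  }
})

test_that("identical sequences have zero divergence and undefined omega", {
  aln <- c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG")
  rec <- ng86_dnds(aln)
  expect_equal(rec$dn, 0)
  expect_equal(rec$ds, 0)
  expect_true(is.na(rec$omega))
  expect_equal(rec$qc_status, "PASS")
})

test_that("a single synonymous change gives dN = 0 and omega = 0", {
  # 2-codon toy: GAA -> GAG is synonymous (Glu)
  rec <- ng86_dnds(c(a = "ATGGAA", b = "ATGGAG"))
  expect_equal(rec$dn, 0)
  expect_equal(rec$omega, 0)
  expect_equal(rec$pairs$Sd, 1)
  expect_equal(rec$pairs$Nd, 0)
  # and a single nonsynonymous change the other way: AAA -> GAA (Lys->Glu)
  rec2 <- ng86_dnds(c(a = "ATGAAA", b = "ATGGAA"))
  expect_equal(rec2$pairs$Nd, 1)
  expect_equal(rec2$pairs$Sd, 0)
  expect_gt(rec2$dn, 0)
})

test_that("pathway counting averages the stop-free orderings", {
  # TTA (Leu) vs CTG (Leu): differs at positions 1 and 3; both orders
  # avoid stops: TTA->CTA(Leu,syn)->CTG(syn) and TTA->TTG(Leu,syn)->CTG(syn)
  rec <- ng86_dnds(c(a = "ATGTTA", b = "ATGCTG"))
  expect_equal(rec$pairs$Sd, 2)
  expect_equal(rec$pairs$Nd, 0)
  # per-pair site counts S + N always total 3 per codon
  expect_equal(rec$pairs$S + rec$pairs$N, 6)
})

test_that("NG86 is symmetric in sequence order", {
  set.seed(44)
  cds <- simulate_cds(simulation_config(seed = 44, n_genes = 5,
                                        omega_background = 0.5,
                                        omega_selected = 0.5),
                      n_taxa = 3, codons_per_gene = 40)
  for (aln in cds$alignments) {
    r1 <- ng86_dnds(aln)
    r2 <- ng86_dnds(rev(aln))
    expect_equal(r1$dn, r2$dn)
    expect_equal(r1$ds, r2$ds)
  }
})

test_that("neutral simulations estimate omega near one", {
  cfg <- simulation_config(seed = 50, n_genes = 200,
                           omega_background = 1, omega_selected = 1,
                           cds_subs_per_codon = 0.3)
  cds <- simulate_cds(cfg, n_taxa = 2, codons_per_gene = 300)
  tab <- dnds_table(cds$alignments)
  expect_true(mean(tab$omega, na.rm = TRUE) > 0.8)
  expect_true(mean(tab$omega, na.rm = TRUE) < 1.2)
})

test_that("purifying selection at omega 0.2 is recovered within band", {
  cfg <- simulation_config(seed = 51, n_genes = 60,
                           omega_background = 0.2, omega_selected = 0.2,
                           cds_subs_per_codon = 0.3)
  cds <- simulate_cds(cfg, n_taxa = 2, codons_per_gene = 300)
  tab <- dnds_table(cds$alignments)
  m <- mean(tab$omega, na.rm = TRUE)
  expect_gt(m, 0.1)
  expect_lt(m, 0.35)
})

test_that("omega estimates above the cap are flagged and excluded", {
  recs <- data.frame(gene_id = c("a", "b", "c", "d"),
                     n_interact = c(TRUE, TRUE, FALSE, FALSE),
                     dn = 1, ds = 1,
                     omega = c(0.5, 6, 0.4, 0.3),
                     qc_status = c("PASS", "OMEGA_GT_CAP", "PASS", "PASS"),
                     stringsAsFactors = FALSE)
  res <- suppressWarnings(dnds_comparison(recs, background_n = 10,
                                          B = 99, seed = 1))
  expect_equal(res$n_target, 1)   # the capped gene is excluded
  expect_equal(res$n_other, 2)
  expect_gte(res$p, 1 / 100)
})

test_that("neighbor joining recovers an additive four-taxon tree", {
  # tree ((A:1,B:2):1,(C:3,D:4)) with internal branch 1
  dm <- matrix(0, 4, 4, dimnames = list(c("A", "B", "C", "D"),
                                        c("A", "B", "C", "D")))
  dm["A", "B"] <- dm["B", "A"] <- 3
  dm["A", "C"] <- dm["C", "A"] <- 5
  dm["A", "D"] <- dm["D", "A"] <- 6
  dm["B", "C"] <- dm["C", "B"] <- 6
  dm["B", "D"] <- dm["D", "B"] <- 7
  dm["C", "D"] <- dm["D", "C"] <- 7
  tr <- nj_tree(dm)
  expect_s3_class(tr, "phylo")
  # additive distances are reproduced exactly by the tree
  cp <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(unname(cp), unname(dm), tolerance = 1e-10)

  # three taxa: closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  cp3 <- ape::cophenetic.phylo(t3)[c("x", "y", "z"), c("x", "y", "z")]
  expect_equal(unname(cp3), unname(d3), tolerance = 1e-10)

  # two taxa: trivial split of the distance
  t2 <- nj_tree(matrix(c(0, 4, 4, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(sum(t2$edge.length), 4)

  # determinism under reruns
  expect_identical(ape::write.tree(nj_tree(dm)),
                   ape::write.tree(nj_tree(dm)))
})

test_that("planted faster protein evolution in N-interact genes is detected", {
  cfg <- simulation_config(seed = 52, n_genes = 80,
                           n_interact_fraction = 0.5,
                           omega_background = 0.2, omega_selected = 0.6)
  cds <- simulate_cds(cfg, n_taxa = 4, codons_per_gene = 100)
  tab <- dnds_table(cds$alignments,
                    cds$truth$gene_id[cds$truth$n_interact])
  res <- suppressWarnings(dnds_comparison(tab, background_n = 100,
                                          B = 499, seed = 2))
  expect_lt(res$p, 0.05)
  expect_gt(res$observed, 0)
})
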