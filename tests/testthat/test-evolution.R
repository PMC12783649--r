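aa20 <- rownames(identity_similarity())

test_that("the similarity matrix is a valid unit-diagonal similarity", {
  s <- blosum50_similarity()
  expect_equal(dim(s), c(20L, 20L))
  expect_equal(unname(diag(s)), rep(1, 20))
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(s, t(s))
  # chemically similar residues are more similar than dissimilar ones
  expect_gt(s["I", "L"], s["I", "D"])
})

test_that("column density matrices are trace-one and PSD", {
  # single residue type: rank one, eigenvalues (1, 0, ..., 0)
  rho <- column_density_matrix(rep("A", 8), identity_similarity())
  ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev[1], 1.0, tolerance = 1e-12)
  expect_equal(sum(abs(ev[-1])), 0, tolerance = 1e-12)
  # uniform frequencies + identity similarity: rho = I/20
  rho_u <- column_density_matrix(aa20, identity_similarity())
  expect_equal(unname(rho_u), diag(20) / 20, tolerance = 1e-12)
  # arbitrary seeded columns against an independently coded construction
  set.seed(13)
  s <- blosum50_similarity()
  for (i in 1:10) {
    col <- sample(aa20, 30, replace = TRUE)
    rho <- column_density_matrix(col, s)
    expect_equal(sum(diag(rho)), 1, tolerance = 1e-10)
    ev <- eigen(rho, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
    expect_equal(sum(ev), 1, tolerance = 1e-10)
    # independent route: explicit matrix product sqrt(P) S sqrt(P)
    f <- as.numeric(table(factor(col, levels = aa20))) / length(col)
    P_half <- diag(sqrt(f))
    M <- P_half %*% s %*% P_half
    expect_equal(unname(rho), M / sum(diag(M)), tolerance = 1e-12)
  }
  expect_null(column_density_matrix(c("-", "-")))
  # gaps are dropped and frequencies renormalized
  expect_equal(column_density_matrix(c("A", "-", "-"), identity_similarity()),
               column_density_matrix("A", identity_similarity()))
})

test_that("Von Neumann entropy closed forms hold in base 20", {
  rho1 <- column_density_matrix(rep("W", 5), identity_similarity())
  expect_equal(vn_entropy(rho1), 0)
  # uniform spectrum: the maximum attainable entropy, exactly 1
  expect_equal(vn_entropy(diag(20) / 20), 1.0, tolerance = 1e-12)
  # two-level case: S = log20(2) by hand
  rho2 <- diag(c(0.5, 0.5, rep(0, 18)))
  expect_equal(vn_entropy(rho2), log(2) / log(20), tolerance = 1e-12)
  expect_error(vn_entropy(diag(20) / 10), "trace")
})

test_that("conservation scores satisfy their definitional identities", {
  seqs <- c(a1 = "ARNA-", a2 = "ARNC-", b1 = "ARNI-", b2 = "ARND-")
  msa <- labeled_msa(seqs, c("a", "a", "b", "b"))
  prof <- conservation_score(msa, identity_similarity())
  expect_equal(prof$score[1], 1)                 # invariant column
  expect_equal(prof$score[1:4] + prof$entropy[1:4], rep(1, 4))
  expect_true(is.na(prof$score[5]))              # all-gap column flagged
  expect_true(prof$low_confidence[5])
  # uniform 20-residue column with identity similarity scores zero
  msa20 <- labeled_msa(stats::setNames(aa20, paste0("s", 1:20)),
                       rep("x", 20))
  prof20 <- conservation_score(msa20, identity_similarity())
  expect_equal(prof20$score[1], 0, tolerance = 1e-12)
})

test_that("conservation decreases as a second residue type grows in", {
  scores <- vapply(c(0, 2, 4, 6, 8, 10), function(k) {
    col <- c(rep("I", 20 - k), rep("D", k))
    1 - vn_entropy(column_density_matrix(col, identity_similarity()))
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_equal(scores[1], 1)
})

test_that("BLOSUM similarity rewards chemically similar mixtures", {
  s <- blosum50_similarity()
  mix_il <- c(rep("I", 10), rep("L", 10))
  mix_id <- c(rep("I", 10), rep("D", 10))
  c_il <- 1 - vn_entropy(column_density_matrix(mix_il, s))
  c_id <- 1 - vn_entropy(column_density_matrix(mix_id, s))
  expect_gt(c_il, c_id)
})

test_that("position classification separates conserved from specific", {
  # col 1: all R everywhere -> fully conserved
  # col 2: class k all W, others F/Y -> perfectly specific for k
  # col 3: class k mixes W and F -> neither
  seqs <- c(k1 = "RWW", k2 = "RWF", o1 = "RFW", o2 = "RYF")
  msa <- labeled_msa(seqs, c("k", "k", "o", "o"))
  res <- classify_positions(msa, 1:3, target_class = "k")
  expect_equal(res$conserved, 1L)
  expect_equal(res$specific, 2L)   # col 3 is neither: target mixes W and F
  seqs2 <- c(k1 = "RW", k2 = "RW", o1 = "RF", o2 = "RY")
  res2 <- classify_positions(labeled_msa(seqs2, c("k", "k", "o", "o")),
                             1:2, "k")
  expect_equal(res2$specific, 2L)
  expect_equal(res2$n_conserved, 1L)
  expect_error(classify_positions(msa, integer(0), "k"), "empty")
  expect_error(classify_positions(msa, 1:2, "zz"), "not present")
})

test_that("specificity ratio hand cases and sentinels", {
  mk <- function(ns, nc) {
    structure(list(n_specific = ns, n_conserved = nc,
                   positions = seq_len(ns + nc),
                   target_class = "k"),
              class = "specificity_result")
  }
  expect_equal(specificity_ratio(mk(1L, 2L)), -1.0)
  expect_equal(specificity_ratio(mk(3L, 3L)), 0.0)
  expect_equal(specificity_ratio(mk(3L, 0L)), Inf)
  expect_equal(specificity_ratio(mk(0L, 2L)), -Inf)
  expect_true(is.nan(specificity_ratio(mk(0L, 0L))))
})

test_that("FASTA + label sidecar round trips into a labeled MSA", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1|d2", "ARND", ">s2|d3", "ARNC"), fa)
  msa <- read_labeled_msa(fa)
  expect_equal(msa$classes, c("d2", "d3"))
  expect_equal(msa$L, 4L)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,class", "s1|d2,alpha", "s2|d3,beta"), csv)
  msa2 <- read_labeled_msa(fa, csv)
  expect_equal(msa2$classes, c("alpha", "beta"))
})
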