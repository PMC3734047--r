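test_that("per-gene ANOVA matches hand arithmetic and stats::aov", {
  design <- mk_design(c("A", "B"))
  x <- tibble::tibble(gene_id = "g1",
                      A_r1 = 10, A_r2 = 12, B_r1 = 20, B_r2 = 22)
  res <- anova_per_gene(x, design)
  # SSB = 100, SSW = 4, F = (100/1)/(4/2) = 50 with df (1, 2)
  expect_equal(res$F_statistic, 50)
  expect_equal(res$p_value, stats::pf(50, 1, 2, lower.tail = FALSE))
  expect_true(res$significant)
  expect_equal(res$mean_A, 11)
  expect_equal(res$mean_B, 21)

  # dual route: random genes against per-gene stats::aov fits
  set.seed(8)
  d4 <- mk_design(c("F16", "F26", "F36", "O26"))
  m <- tibble::tibble(gene_id = sprintf("g%02d", 1:5))
  for (s in d4$sample_id) m[[s]] <- rlnorm(5, log(300), 0.4)
  res4 <- anova_per_gene(m, d4)
  cond <- factor(d4$condition)
  for (i in 1:5) {
    fit <- stats::aov(unlist(m[i, d4$sample_id]) ~ cond)
    p_aov <- summary(fit)[[1]][["Pr(>F)"]][1]
    expect_equal(res4$p_value[i], p_aov, tolerance = 1e-8)
  }
})

test_that("ANOVA handles degenerate genes and is label-symmetric", {
  d4 <- mk_design(c("F16", "F26", "F36", "O26"))
  m <- tibble::tibble(gene_id = c("flat", "vary"))
  for (s in d4$sample_id) m[[s]] <- c(7, rlnorm(1, 5, 0.3))
  res <- anova_per_gene(m, d4)
  expect_equal(res$p_value[res$gene_id == "flat"], 1)
  expect_false(res$significant[res$gene_id == "flat"])

  # consistently permuting condition labels leaves p values unchanged
  d_perm <- d4
  d_perm$condition <- dplyr::recode(d4$condition, F16 = "O26", O26 = "F16",
                                    F26 = "F36", F36 = "F26")
  res_p <- anova_per_gene(m, d_perm)
  expect_equal(res_p$p_value, res$p_value)

  expect_error(anova_per_gene(m, mk_design(c("F16", "F26"), replicates = 1)),
               "replicates")
})

test_that("rejection rate grows with programmed effect size", {
  d4 <- mk_design(c("F16", "F26", "F36", "O26"))
  rate_at <- function(effect, n_genes = 1500, seed = 31) {
    set.seed(seed)
    m <- tibble::tibble(gene_id = sprintf("g%04d", seq_len(n_genes)))
    shift <- c(F16 = 0, F26 = effect, F36 = 0, O26 = -effect)
    for (i in seq_len(nrow(d4))) {
      s <- d4$sample_id[i]
      m[[s]] <- rlnorm(n_genes, log(500) + shift[[d4$condition[i]]], 0.2)
    }
    mean(anova_per_gene(m, d4)$significant)
  }
  rates <- vapply(c(0, 0.2, 0.5), rate_at, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_gt(rates[3], 0.5)
})

test_that("expression categories follow the strict RPKM thresholds", {
  design <- mk_design("F16")
  x <- tibble::tibble(gene_id = c("zero", "at250", "mid", "at20k", "above"),
                      F16_r1 = c(0, 250, 5000, 20000, 20001),
                      F16_r2 = c(0, 250, 5000, 20000, 20001))
  cls <- classify_expression(x, design)
  got <- stats::setNames(cls$category, cls$gene_id)
  expect_identical(unname(got["zero"]), "silent_or_weak")
  expect_identical(unname(got["at250"]), "moderate")   # threshold is < 250
  expect_identical(unname(got["mid"]), "moderate")
  expect_identical(unname(got["at20k"]), "moderate")   # threshold is > 20000
  expect_identical(unname(got["above"]), "high")
  expect_true(all(cls$high_in_any == (cls$gene_id == "above")))
  expect_error(classify_expression(x, design, weak_max = 300, high_min = 200))
})

test_that("ratio tables report fold changes with pseudocount guards", {
  design <- mk_design(c("F16", "F26"))
  x <- tibble::tibble(gene_id = c("up", "zero_den", "down"),
                      F16_r1 = c(10, 0, 100), F16_r2 = c(10, 0, 100),
                      F26_r1 = c(370, 50, 25), F26_r2 = c(370, 50, 25))
  rt <- expression_ratios(x, "F26", "F16", design)
  expect_false("zero_den" %in% rt$gene_id)   # skipped at pseudo = 0
  expect_equal(rt$ratio[rt$gene_id == "up"], 37)
  expect_identical(rt$direction[rt$gene_id == "down"], "down")
  expect_true(!is.unsorted(rev(rt$ratio)))   # sorted descending

  rt1 <- expression_ratios(x, "F26", "F16", design, pseudo = 1)
  expect_true(all(is.finite(rt1$ratio)))
  expect_equal(rt1$ratio[rt1$gene_id == "zero_den"], 51)
  expect_error(expression_ratios(x, "F99", "F16", design), "unknown")
})

test_that("log2 matrix is finite, monotone, and filters by significance", {
  design <- mk_design(c("A", "B"))
  x <- tibble::tibble(gene_id = c("g1", "g2"),
                      A_r1 = c(0, 1023), A_r2 = c(0, 1023),
                      B_r1 = c(0, 1023), B_r2 = c(0, 1023))
  lm <- log2_matrix(x, pseudo = 1)
  expect_equal(lm$A_r1, c(0, 10))
  expect_true(all(is.finite(as.matrix(lm[-1]))))

  fake_sig <- tibble::tibble(gene_id = c("g1", "g2"),
                             significant = c(FALSE, TRUE))
  expect_identical(log2_matrix(x, significant = fake_sig)$gene_id, "g2")
  expect_error(log2_matrix(x, pseudo = 0))
})

test_that("sample clustering pairs samples from the same profile first", {
  set.seed(12)
  n <- 200
  profile1 <- rnorm(n, 8, 2)
  profile2 <- profile1 + rnorm(n, 0, 4)     # distant profile
  mk <- function(p, sd) p + rnorm(n, 0, sd)
  m <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                      a1 = mk(profile1, 0.3), a2 = mk(profile1, 0.3),
                      b1 = mk(profile2, 0.3))
  cl <- cluster_samples(m)
  expect_setequal(cl$nearest_pair$samples, c("a1", "a2"))

  # duplicated column sits at distance zero from its twin
  m2 <- dplyr::mutate(m, a3 = .data$a1)
  cl2 <- cluster_samples(m2)
  d <- as.matrix(cl2$dist)
  expect_equal(d["a1", "a3"], 0, tolerance = 1e-12)

  # permuting columns permutes labels but not the topology
  cl_perm <- cluster_samples(m[c("gene_id", "b1", "a2", "a1")])
  expect_equal(sort(cl_perm$hclust$height), sort(cl$hclust$height))
  expect_setequal(cl_perm$nearest_pair$samples, c("a1", "a2"))

  expect_warning(cluster_samples(tibble::tibble(gene_id = c("g1", "g2"),
                                                s1 = c(1, 1), s2 = c(1, 1),
                                                s3 = c(1, 1))),
                 "constant")
  expect_error(cluster_samples(m[c("gene_id", "a1", "a2")]), ">= 3")
})

test_that("tidy and glance summarise fitted objects", {
  d4 <- mk_design(c("A", "B"))
  set.seed(2)
  m <- tibble::tibble(gene_id = c("g1", "g2"))
  for (s in d4$sample_id) m[[s]] <- rlnorm(2, 5, 0.3)
  an <- anova_per_gene(m, d4)
  td <- tidy(an)
  expect_named(td, c("gene_id", "statistic", "p.value", "significant"))
  gl <- glance(an)
  expect_equal(gl$n_genes, 2L)
  expect_equal(gl$df_between, 1)
})
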