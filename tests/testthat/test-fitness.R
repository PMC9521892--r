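resolve_genotype <- daisydrive:::resolve_genotype

test_that("dominant fitness multiplies once per distinct cost-bearing allele", {
  d <- drive_preset("direct_dcd")
  fp <- fitness_preset("fig_defaults", d)
  wt <- genotype(A = c("T", "T"), B = c("T", "T"), C = c("T", "T"))
  expect_equal(genotype_fitness(wt, "female", fp, d), 1)
  het <- genotype(A = c("E", "T"), B = c("N^A", "T"), C = c("G^B", "T"))
  expect_equal(genotype_fitness(het, "female", fp, d), 0.9 * 0.95 * 0.95)
  hom <- genotype(A = c("E", "E"), B = c("N^A", "N^A"), C = c("G^B", "G^B"))
  expect_equal(genotype_fitness(hom, "male", fp, d), 0.9 * 0.95 * 0.95)  # applied once
  lethal <- genotype(A = c("R2", "T"), B = c("T", "T"), C = c("T", "T"))
  expect_equal(genotype_fitness(lethal, "female", fp, d), 0)
})

test_that("recessive costs trigger on two loss-of-function alleles at the locus", {
  d <- drive_preset("direct_dcd")
  fp <- fitness_params(dominant = list(A = c(E = 0.9)),
                       recessive = list(A = 0.5))
  gf <- function(a1, a2) {
    genotype_fitness(genotype(A = c(a1, a2), B = c("T", "T"), C = c("T", "T")),
                     "female", fp, d)
  }
  expect_equal(gf("E", "E"), 0.45)   # 0.9 dominant (once) x 0.5 recessive
  expect_equal(gf("E", "R2"), 0.45)
  expect_equal(gf("R2", "R2"), 0.5)
  expect_equal(gf("E", "T"), 0.9)    # heterozygote: dominant cost only
  expect_equal(gf("E", "R1"), 0.9)   # R1 is functional, no recessive trigger
})

test_that("sex-specific values pick the right sex", {
  d <- drive_preset("spd")
  fp <- fitness_params(dominant = list(A = list(`N^A` = c(female = 0.5, male = 1))))
  g <- genotype(A = c("N^A", "T"))
  expect_equal(genotype_fitness(g, "female", fp, d), 0.5)
  expect_equal(genotype_fitness(g, "male", fp, d), 1)
  sp <- enumerate_states(d)
  th <- fitness_vector(sp, fp)
  expect_equal(sum(th$female < 1), sum(sp$drive_at[, "A"]))
  expect_true(all(th$male == 1))
})

test_that("mosaic fitness averages outcome fitness over the deposition row", {
  spd <- drive_preset("spd")
  sp <- enumerate_states(spd, deposition = TRUE)
  fp <- fitness_preset("fig_defaults", spd)
  theta <- fitness_vector(sp, fp)$female
  dep <- repair_params(kappa_dep = 0.25, beta_dep = 0.1)
  K <- conversion_matrix(sp, dep, "embryo")
  w <- mosaic_fitness(K, theta)
  # identity rows keep their zygotic fitness
  ident <- Matrix::diag(K) == 1
  expect_equal(w[ident], theta[ident])
  # a TT zygote under a deposited complex survives iff no R2 emerges: 0.775^2
  g <- resolve_genotype(sp, genotype(A = c("T", "T"), cas9_maternal = 1,
                                     grnas_maternal = "A"))
  i <- daisydrive:::state_index(sp, g[["geno"]], g[["tag"]])
  expect_equal(w[i], 0.775^2)
  # a drive heterozygote is hit harder than its zygotic fitness (haplolethal T)
  gh <- resolve_genotype(sp, genotype(A = c("T", "N^A"), cas9_maternal = 1,
                                      grnas_maternal = "A"))
  ih <- daisydrive:::state_index(sp, gh[["geno"]], gh[["tag"]])
  expect_lt(w[ih], theta[ih])
})

test_that("the embryonic matrix D combines deposition and mosaic survival", {
  spd <- drive_preset("spd")
  sp <- enumerate_states(spd)
  fp <- fitness_preset("fig_defaults", spd)
  theta <- fitness_vector(sp, fp)$female
  # no deposition: D is the fitness diagonal
  K <- Matrix::Diagonal(sp$d)
  D <- build_D(K, theta)
  expect_equal(as.numeric(Matrix::diag(D)), theta)
  # all fitness 1: D reduces to K
  D1 <- build_D(K, rep(1, sp$d))
  expect_equal(as.numeric(Matrix::diag(D1)), rep(1, sp$d))
  # selection removes a lethal class entirely after normalisation
  z <- rep(0, sp$d)
  g_ok <- resolve_genotype(sp, genotype(A = c("T", "T")))
  g_dead <- resolve_genotype(sp, genotype(A = c("R2", "T")))
  z[g_ok[["geno"]]] <- 0.5
  z[g_dead[["geno"]]] <- 0.5
  e <- as.numeric(z %*% D)
  e <- e / sum(e)
  expect_equal(e[g_ok[["geno"]]], 1)
})

test_that("with neutral fitness and no deposition the embryo stage is conserved", {
  sp <- enumerate_states(drive_preset("direct_dcd"))
  D <- build_D(Matrix::Diagonal(sp$d), rep(1, sp$d))
  z <- stats::runif(sp$d)
  z <- z / sum(z)
  expect_equal(as.numeric(z %*% D), z)
})

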