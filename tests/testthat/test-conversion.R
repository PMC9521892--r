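test_that("the repair split partitions the fate of a cut T allele", {
  expect_equal(repair_split(repair_params()),
               c(hdr = 0.95, r1 = 0.005, r2 = 0.045, uncut = 0))
  expect_equal(repair_split(repair_params(kappa = 0)),
               c(hdr = 0, r1 = 0, r2 = 0, uncut = 1))
  expect_equal(repair_split(repair_params(kappa = 0.85)),
               c(hdr = 0.8075, r1 = 0.00425, r2 = 0.03825, uncut = 0.15))
  p <- repair_params(alpha = 0.6, beta = 0.3)
  expect_equal(p$alpha + p$mu + p$nu, 1)
  expect_equal(sum(repair_split(p)), 1)
  expect_error(repair_params(kappa = 1.2), "\\[0, 1\\]")
})

test_that("cut eligibility needs gRNA, target T and nuclease in one individual", {
  direct <- drive_preset("direct_dcd")
  indirect <- drive_preset("indirect_dcd")
  # phantom cutting: an isolated direct-DCD B element cuts a TT A locus
  g <- genotype(A = c("T", "T"), B = c("N^A", "T"), C = c("T", "T"))
  expect_true(cut_eligible(g, "A", "germline", direct))
  # the indirect B element alone has no gRNA at all
  g2 <- genotype(A = c("T", "T"), B = c("N", "T"), C = c("T", "T"))
  expect_false(cut_eligible(g2, "A", "germline", indirect))
  # embryo stage: deposited Cas9:gRNA complex suffices without any transgene
  g3 <- genotype(A = c("T", "T"), cas9_maternal = 1, grnas_maternal = "A")
  expect_true(cut_eligible(g3, "A", "embryo", drive_preset("spd")))
  # ... but not in the germline, and not without the maternal Cas9
  expect_false(cut_eligible(g3, "A", "germline", drive_preset("spd")))
  g4 <- genotype(A = c("T", "T"))
  expect_false(cut_eligible(g4, "A", "embryo", drive_preset("spd")))
})

test_that("germline conversion rows follow the per-allele cut/repair rules", {
  spd <- drive_preset("spd")
  row <- germline_row(genotype(A = c("T", "N^A")), spd)
  expect_equal(sum(row), 1)
  expect_equal(unname(row[canonical_key(genotype(A = c("N^A", "N^A")))]), 0.95)
  expect_equal(unname(row[canonical_key(genotype(A = c("R1", "N^A")))]), 0.005)
  expect_equal(unname(row[canonical_key(genotype(A = c("R2", "N^A")))]), 0.045)
  # no T anywhere: identity
  hom <- genotype(A = c("N^A", "N^A"))
  expect_equal(germline_row(hom, spd), stats::setNames(1, canonical_key(hom)))
  # eligible TT locus, kappa = 0.85, no HDR: per-allele T .15 / R1 .085 / R2 .765
  direct <- drive_preset("direct_dcd")
  g <- genotype(A = c("T", "T"), B = c("N^A", "R1"), C = c("T", "T"))
  row <- germline_row(g, direct, repair_params(kappa = 0.85))
  expect_equal(sum(row), 1)
  a_pair <- function(a1, a2) {
    canonical_key(genotype(A = c(a1, a2), B = c("N^A", "R1"), C = c("T", "T")))
  }
  expect_equal(unname(row[a_pair("T", "T")]), 0.15^2)
  expect_equal(unname(row[a_pair("T", "R1")]), 2 * 0.15 * 0.085)
  expect_equal(unname(row[a_pair("T", "R2")]), 2 * 0.15 * 0.765)
  expect_equal(unname(row[a_pair("R1", "R1")]), 0.085^2)
  expect_equal(unname(row[a_pair("R1", "R2")]), 2 * 0.085 * 0.765)
  expect_equal(unname(row[a_pair("R2", "R2")]), 0.765^2)
})

test_that("loci convert independently within one germline", {
  # direct-DCD triple heterozygote: A and B convert, C segregates untouched
  direct <- drive_preset("direct_dcd")
  g <- genotype(A = c("T", "E"), B = c("T", "N^A"), C = c("T", "G^B"))
  row <- germline_row(g, direct)
  expect_equal(sum(row), 1)
  target <- canonical_key(genotype(A = c("E", "E"), B = c("N^A", "N^A"),
                                   C = c("T", "G^B")))
  # A: kappa*alpha = .95; B is a neutral locus, all non-HDR is R1: still .95
  expect_equal(unname(row[target]), 0.95 * 0.95)
  r1b <- canonical_key(genotype(A = c("E", "E"), B = c("R1", "N^A"),
                                C = c("T", "G^B")))
  expect_equal(unname(row[r1b]), 0.95 * 0.05)
  # no R2 outcomes at the neutral B locus
  keys <- names(row)
  expect_false(any(grepl("B:R2", keys, fixed = TRUE)))
})

test_that("sequential TT cutting lets HDR regenerate and then copy the first repair", {
  direct <- drive_preset("direct_dcd")
  g <- genotype(A = c("T", "T"), B = c("N^A", "R1"), C = c("T", "T"))
  k <- 0.85; a <- 0.95; b <- 0.1
  mu <- (1 - a) * b; nu <- (1 - a) * (1 - b)
  row <- germline_row(g, direct, repair_params(kappa = k, tt_mode = "sequential"))
  expect_equal(sum(row), 1)
  a_pair <- function(a1, a2) {
    canonical_key(genotype(A = c(a1, a2), B = c("N^A", "R1"), C = c("T", "T")))
  }
  # first allele: T w.p. (1-k) + k*a (HDR template is the homologous T)
  pT <- (1 - k) + k * a
  # {T,T}: first stays/reverts to T and second uncut or HDR-copies the T
  expect_equal(unname(row[a_pair("T", "T")]), pT * (1 - k + k * a))
  # {R1,R1}: first to R1 then second HDR-copies R1 or mutates to R1
  expect_equal(unname(row[a_pair("R1", "R1")]), k * mu * (k * a + k * mu))
  # {T,R2}: either order of (stay T, become R2)
  expect_equal(unname(row[a_pair("T", "R2")]),
               pT * k * nu + k * nu * (1 - k))
})

test_that("deposition rows use the embryonic rates and the maternal tag", {
  spd <- drive_preset("spd")
  dep <- repair_params(kappa_dep = 0.25, beta_dep = 0.1)
  # no deposition tag: identity
  g0 <- genotype(A = c("T", "T"))
  expect_equal(deposition_row(g0, spd, dep),
               stats::setNames(1, canonical_key(g0)))
  # deposited complex on a TT genotype: per-allele T .75 / R1 .025 / R2 .225
  g <- genotype(A = c("T", "T"), cas9_maternal = 1, grnas_maternal = "A")
  row <- deposition_row(g, spd, dep)
  expect_equal(sum(row), 1)
  key <- function(a1, a2) {
    canonical_key(genotype(A = c(a1, a2), cas9_maternal = 1, grnas_maternal = "A"))
  }
  expect_equal(unname(row[key("T", "T")]), 0.75^2)
  expect_equal(unname(row[key("T", "R1")]), 2 * 0.75 * 0.025)
  expect_equal(unname(row[key("R2", "R2")]), 0.225^2)
  # Cas9-only deposition with no genomic gRNA: identity
  cas_only <- genotype(A = c("T", "T"), cas9_maternal = 1)
  nodep <- repair_params(kappa_dep = 0.25, grna_deposition = FALSE)
  expect_equal(deposition_row(cas_only, spd, nodep),
               stats::setNames(1, canonical_key(cas_only)))
  # ... but a genomically inherited gRNA pairs with the deposited Cas9
  g_inherit <- genotype(A = c("T", "N^A"), cas9_maternal = 1)
  row2 <- deposition_row(g_inherit, spd, nodep)
  expect_gt(length(row2), 1L)
  expect_equal(sum(row2), 1)
})

test_that("shadow drive borrows the germline HDR rate, co-deposition takes precedence", {
  spd <- drive_preset("spd")
  shadow <- repair_params(kappa_dep = 0.25, beta_dep = 0.1, shadow_drive = TRUE)
  # paternally inherited gRNA (genomic N^A not in the maternal deposit)
  g <- genotype(A = c("T", "N^A"), cas9_maternal = 1)
  row <- deposition_row(g, spd, shadow)
  hdr_key <- canonical_key(genotype(A = c("N^A", "N^A"), cas9_maternal = 1))
  expect_equal(unname(row[hdr_key]), 0.25 * 0.95)
  # same genotype with the gRNA co-deposited: alpha_dep = 0, no homing
  g2 <- genotype(A = c("T", "N^A"), cas9_maternal = 1, grnas_maternal = "A")
  row2 <- deposition_row(g2, spd, shadow)
  hdr_key2 <- canonical_key(genotype(A = c("N^A", "N^A"), cas9_maternal = 1,
                                     grnas_maternal = "A"))
  expect_false(hdr_key2 %in% names(row2))
})

test_that("ideal homing converts drive heterozygotes with certainty", {
  ideal <- repair_params(kappa = 1, alpha = 1)
  for (nm in c("spd", "indirect_dcd")) {
    sp <- enumerate_states(drive_preset(nm))
    C <- conversion_matrix(sp, ideal, "germline")
    em <- daisydrive:::.eligible_matrix(sp, ideal, "germline")
    for (i in which(apply(em$eligible, 1, any))) {
      row <- C[i, ]
      j <- which(row > 0)
      # a fully eligible het ends with no T at its eligible loci
      lab <- sp$loci[em$eligible[i, ]]
      for (l in lab) {
        if (sp$nT[i, l] == 1L) {
          expect_true(all(sp$nT[j, l] == 0L))
        }
      }
    }
  }
})

test_that("only the direct design can cut locus A without an A drive allele", {
  params <- repair_params(kappa = 0.85)
  scan <- function(name) {
    sp <- enumerate_states(drive_preset(name))
    em <- daisydrive:::.eligible_matrix(sp, params, "germline")
    any(em$eligible[, "A"] & !sp$drive_at[, "A"])
  }
  expect_true(scan("direct_dcd"))
  expect_false(scan("indirect_dcd"))
})

test_that("sampled per-allele cut/repair events reproduce a germline row", {
  # Monte-Carlo oracle for the SPD heterozygote at kappa = 0.85
  set.seed(421)
  n <- 1e6
  kappa <- 0.85
  conv <- sample_repair(n, rep("N", n), kappa, 0.95, 0.1)
  emp <- table(conv) / n
  row <- germline_row(genotype(A = c("T", "N^A")), drive_preset("spd"),
                      repair_params(kappa = kappa))
  expected <- c(N = 0.8075, R1 = 0.00425, R2 = 0.03825, T = 0.15)
  for (al in names(expected)) {
    p_pkg <- if (al == "N") {
      unname(row[canonical_key(genotype(A = c("N^A", "N^A")))])
    } else {
      unname(row[canonical_key(genotype(A = c(al, "N^A")))])
    }
    se <- sqrt(expected[[al]] * (1 - expected[[al]]) / n)
    expect_lt(abs(emp[[al]] - p_pkg), 3 * se + 1e-12)
  }
})
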