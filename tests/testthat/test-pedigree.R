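test_that("build_pedigree validates structure, cycles and sex conflicts", {
  trio <- build_pedigree(data.frame(id = c("c", "s", "d"),
                                    sire = c("s", NA, NA),
                                    dam = c("d", NA, NA)))
  expect_equal(nrow(trio), 3L)
  expect_equal(trio$sex[trio$id == "s"], "M")
  expect_error(build_pedigree(data.frame(id = c("a", "a"), sire = NA, dam = NA)),
               "duplicate")
  expect_error(build_pedigree(data.frame(id = c("a", "b"),
                                         sire = c("b", "a"),
                                         dam = c(NA, NA))), "cycle")
  expect_error(build_pedigree(data.frame(id = c("a", "b", "c"),
                                         sire = c(NA, "a", NA),
                                         dam = c(NA, NA, "a"))),
               "sex conflict")
  expect_error(build_pedigree(data.frame(id = c("a", "b"),
                                         sire = c(NA, "a"), dam = c(NA, NA),
                                         sex = c("F", "M"))), "sex conflict")
})

test_that("additive relationship reproduces textbook coefficients", {
  ped <- build_pedigree(data.frame(
    id = c("s", "d", "c1", "c2", "inbred"),
    sire = c(NA, NA, "s", "s", "c1"),
    dam = c(NA, NA, "d", "d", "c2")))
  A <- additive_relationship(ped)
  expect_equal(A["s", "c1"], 0.5)          # parent-offspring
  expect_equal(A["c1", "c2"], 0.5)         # full siblings
  expect_equal(A["inbred", "inbred"], 1.25)  # offspring of full-sib mating
  expect_equal(A["s", "d"], 0)
  expect_true(isSymmetric(A))
  expect_true(all(diag(A) >= 1))
  expect_true(all(A >= 0))
})

test_that("generation truncation never increases relationship entries", {
  co <- small_cohort()
  ids <- utils::tail(co$pedigree$id, 25)
  A2 <- additive_relationship(co$pedigree, ids, max_generations = 2)
  A3 <- additive_relationship(co$pedigree, ids, max_generations = 3)
  A9 <- additive_relationship(co$pedigree, ids, max_generations = 9)
  expect_true(all(A3 - A2 >= -1e-12))
  expect_true(all(A9 - A3 >= -1e-12))
})

test_that("tabular relationships agree with a gene-dropping oracle", {
  # independent oracle: drop unique founder alleles down the pedigree many
  # times; kinship(i, j) = P(two random alleles are identical by descent)
  set.seed(2024)
  ped <- as.data.frame(simulate_pedigree(sim_config(
    n_generations = 3, n_founders = 12, mean_litter_size = 2,
    sire_fraction = 0.8, dam_fraction = 1)))
  ped <- ped[seq_len(min(30, nrow(ped))), ]
  ped$sire[!ped$sire %in% ped$id] <- NA
  ped$dam[!ped$dam %in% ped$id] <- NA
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  n_drop <- 10000L
  match_sum <- matrix(0, n, n)
  for (rep in seq_len(n_drop)) {
    al <- matrix(0L, n, 2)
    for (i in seq_len(n)) {
      if (is.na(si[i])) {
        al[i, ] <- c(2L * i - 1L, 2L * i)
      } else {
        al[i, 1] <- al[si[i], sample.int(2L, 1L)]
        al[i, 2] <- al[di[i], sample.int(2L, 1L)]
      }
    }
    for (a in 1:2) for (b in 1:2) {
      match_sum <- match_sum + outer(al[, a], al[, b], "==")
    }
  }
  kin_hat <- match_sum / (4 * n_drop)
  A_hat <- 2 * kin_hat    # off-diag 2*kinship; diag 2*(1+F)/2 = 1+F
  A <- additive_relationship(ped, ped$id, max_generations = 10)
  expect_lt(max(abs(A - A_hat)), 0.03)    # ~4 sd of binomial MC error
})

test_that("relationship categories are reported from the first id's view", {
  ped <- toy_ped()
  expect_true("parent" %in% relation_category(ped, "S", "X"))
  expect_true("offspring" %in% relation_category(ped, "X", "S"))
  expect_true("full-sib" %in% relation_category(ped, "SIB", "X"))
  expect_true("half-sib" %in% relation_category(ped, "HS", "X"))
  expect_true("grandparent" %in% relation_category(ped, "gp1", "X"))
  expect_true("great-grandparent" %in% relation_category(ped, "gp1", "KID"))
  expect_true("grandchild" %in% relation_category(ped, "KID", "S"))
  expect_true("avuncular" %in% relation_category(ped, "AUNT", "X"))
  expect_error(relation_category(ped, "nope", "X"), "unknown id")
  expect_error(relation_category(ped, "X", "X"), "differ")
})

test_that("cohort classification applies the carrier and exclusion rules in order", {
  ped <- toy_ped()
  genotyped <- c("S", "D", "SIB", "KID", "gp1", "U1", "U2", "AUNT", "HS")
  st <- classify_cohort(ped, case_ids = "X", genotyped_ids = genotyped)
  get <- function(id) st$status[st$id == id]
  expect_equal(get("S"), "carrier")        # parent of a case
  expect_equal(get("D"), "carrier")
  expect_equal(get("KID"), "carrier")      # offspring of a case
  expect_equal(get("SIB"), "excluded_relative")
  expect_equal(get("HS"), "excluded_relative")
  expect_equal(get("gp1"), "excluded_relative")  # grandparent of one case
  expect_equal(get("AUNT"), "excluded_relative")
  expect_equal(get("U1"), "control")
  expect_equal(st$y[st$id == "S"], 1L)
  expect_equal(st$y[st$id == "U1"], 0L)
  expect_true(all(is.na(st$y[st$status == "excluded_relative"])))
  # grandparent of two cases is promoted to carrier (rule precedence)
  st2 <- classify_cohort(ped, case_ids = c("X", "SIB"), genotyped_ids = genotyped)
  expect_equal(st2$status[st2$id == "gp1"], "carrier")
  expect_equal(st2$reason[st2$id == "gp1"], "grandparent_of_two_cases")
})

test_that("pihat exclusion and diagnosis exclusions carry reasons", {
  ped <- toy_ped()
  genotyped <- c("X", "U1", "U2")
  ph <- data.frame(id1 = "X", id2 = "U1", pihat = 0.3)
  st <- classify_cohort(ped, "X", genotyped, pihat = ph)
  expect_equal(st$status[st$id == "U1"], "excluded_relative")
  expect_equal(st$reason[st$id == "U1"], "pihat")
  expect_equal(st$status[st$id == "U2"], "control")
  diag_tab <- data.frame(id = c("X", "U1"), ambiguous = c(TRUE, FALSE),
                         immunophenotype = c(NA, "T"))
  st2 <- classify_cohort(ped, c("X", "U1"), genotyped, diagnoses = diag_tab)
  expect_equal(st2$status[st2$id == "X"], "excluded_diagnosis")
  expect_equal(st2$reason[st2$id == "X"], "ambiguous_diagnosis")
  expect_equal(st2$status[st2$id == "U1"], "excluded_diagnosis")
  expect_equal(st2$reason[st2$id == "U1"], "t_cell")
})

test_that("classification is independent of input ordering", {
  ped <- toy_ped()
  genotyped <- c("S", "D", "SIB", "KID", "gp1", "U1", "U2", "AUNT", "HS")
  a <- classify_cohort(ped, "X", genotyped)
  b <- classify_cohort(ped, "X", rev(genotyped))
  expect_identical(a, b)
})

test_that("simulated heterozygous parents of affected dogs are always carriers", {
  co <- small_cohort()
  cases <- co$clinical$id[co$clinical$affected]
  skip_if(length(cases) < 2)
  st <- suppressMessages(classify_cohort(co$pedigree, cases, co$pedigree$id))
  ped <- as.data.frame(co$pedigree)
  par_of_case <- setdiff(unique(c(ped$sire[ped$id %in% cases],
                                  ped$dam[ped$id %in% cases])), NA)
  het_parents <- intersect(par_of_case,
                           co$truth$id[co$truth$risk_genotype == 1L])
  het_parents <- setdiff(het_parents, cases)
  expect_true(all(st$status[match(het_parents, st$id)] == "carrier"))
})

test_that("common ancestors are ranked and disjoint families yield none", {
  ped <- toy_ped()
  ca <- common_ancestors(ped, c("X", "SIB"))
  expect_true(all(c("S", "D") %in% ca$id))
  # the nearest common ancestors (the parents) head the list
  expect_true(all(ca$id[1:2] %in% c("S", "D")))
  expect_equal(nrow(common_ancestors(ped, c("X", "U1"))), 0L)
})
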