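test_that("reduced enterocyte network is deterministic, feasible on
           open exchanges, and inert when closed", {
  net <- build_reduced_siec()
  expect_identical(net, build_reduced_siec())
  expect_equal(n_metabolites(net), 66L)
  sol <- fba(net)                         # biomass demand
  expect_equal(sol$status, "optimal")
  expect_gt(sol$objective, 0)
  # closing every exchange leaves only the zero flux vector
  ex <- grep("^EX_", net$rxns$id, value = TRUE)
  closed <- stats::setNames(lapply(ex, function(x) c(0, 0)), ex)
  s0 <- fba(net, extra_bounds = closed)
  expect_equal(s0$status, "optimal")
  expect_equal(max(abs(s0$fluxes)), 0, tolerance = 1e-9)
})

test_that("the levodopa module adds exactly 36 mass-balanced transport
           reactions and refuses double application", {
  net <- build_reduced_siec()
  net2 <- add_levodopa_module(net)
  expect_equal(n_reactions(net2) - n_reactions(net), 36L)
  expect_error(add_levodopa_module(net2), "already")
  # each antiport column is a strict 1:1 exchange: two reactants, two
  # products, zero net stoichiometry
  anti <- grep("LDOPA_(lum|bl)_anti_", net2$rxns$id, value = TRUE)
  expect_length(anti, 33L)
  for (id in anti) {
    col <- net2$S[, match(id, net2$rxns$id)]
    expect_equal(sum(col), 0)
    expect_equal(sum(col > 0), 2L)
    expect_equal(sum(col < 0), 2L)
    # one-to-one: all coefficients unit
    expect_true(all(abs(col[col != 0]) == 1))
  }
})

test_that("the kidney/brain extension requires the levodopa module and
           balances absorbed flux across its three fates", {
  expect_error(extend_brain_kidney(build_reduced_siec()), "module")
  star <- siec_star()
  expect_true(all(c("levodopa[s]", "levodopa[brain]") %in%
                    star$mets$id))
  # zero luminal levodopa -> zero brain delivery
  s0 <- fba(star, objective = "LDOPA_brain",
            extra_bounds = list(EX_levodopa_l = c(0, 0)))
  expect_equal(s0$objective, 0, tolerance = 1e-9)
  # brain + renal + residual = absorbed (systemic) flux
  ref <- fasting_reference_fba(star)
  expect_equal(ref$brain + ref$renal + ref$residual, ref$systemic,
               tolerance = 1e-8)
})

test_that("SBML round trip preserves stoichiometry and bounds exactly,
           and the packaged network file loads", {
  net <- reduced_with_levodopa()
  f <- tempfile(fileext = ".xml")
  write_network(net, f)
  back <- load_network(f)
  expect_identical(back$rxns$id, net$rxns$id)
  expect_identical(back$mets$id, net$mets$id)
  expect_equal(unname(back$S), unname(net$S))
  expect_identical(back$rxns$lb, net$rxns$lb)
  expect_identical(back$rxns$ub, net$rxns$ub)
  pkg_file <- system.file("extdata", "reduced_siec_sbml.xml",
                          package = "levogut")
  expect_true(nzchar(pkg_file))
  fixture <- load_network(pkg_file)
  expect_equal(n_reactions(fixture), n_reactions(build_reduced_siec()))
  # the packaged file is the base network: the module applies on top
  expect_equal(n_reactions(add_levodopa_module(fixture)) -
                 n_reactions(fixture), 36L)
  expect_error(load_network(tempfile()), "parse")
  bad <- tempfile(fileext = ".xml")
  writeLines("<sbml><model/></sbml>", bad)
  expect_error(load_network(bad), "species")
})

test_that("competition shares follow affinity ranks and amounts", {
  cat <- transporter_catalog()
  # sole substrate takes the full carrier
  expect_equal(competition_share(1, numeric(), cat$luminal_antiporter,
                                 cat$luminal_levodopa_rank), 1)
  # saturating cystine suppresses the share below 5%
  sat <- competition_share(1, c(cystine = 1000),
                           cat$luminal_antiporter,
                           cat$luminal_levodopa_rank)
  expect_lt(sat, 0.05)
  # ornithine (lowest affinity) leaves a larger share than cystine
  s_orn <- competition_share(1, c(ornithine = 50),
                             cat$luminal_antiporter,
                             cat$luminal_levodopa_rank)
  s_cys <- competition_share(1, c(cystine = 50),
                             cat$luminal_antiporter,
                             cat$luminal_levodopa_rank)
  expect_gt(s_orn, s_cys)
  # monotone: share non-increasing in any competitor amount
  set.seed(21)
  for (i in 1:10) {
    base_amt <- stats::setNames(runif(3, 0, 20),
                                sample(names(cat$luminal_antiporter), 3))
    sp <- sample(names(cat$luminal_antiporter), 1)
    bumped <- base_amt
    bumped[sp] <- (if (is.na(bumped[sp])) 0 else bumped[sp]) + 5
    expect_lte(competition_share(1, bumped, cat$luminal_antiporter,
                                 cat$luminal_levodopa_rank),
               competition_share(1, base_amt, cat$luminal_antiporter,
                                 cat$luminal_levodopa_rank) + 1e-12)
  }
  expect_error(competition_share(1, c(foo = 1),
                                 cat$luminal_antiporter,
                                 cat$luminal_levodopa_rank), "unknown")
  # acidic amino acids sit on no carrier: share unchanged
  expect_equal(competition_share(1, c(asp = 100, glu = 100),
                                 cat$luminal_antiporter,
                                 cat$luminal_levodopa_rank), 1)
})
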