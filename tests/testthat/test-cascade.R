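test_that("sequential contributions reproduce the published cascades", {
  # full prezygotic cascade, yellow-flowered species
  cr <- sequentialContributions(c(0.81, 0.13, 0, 0.9945),
    stages = c("Geographic", "Phenology", "Pollinator assemblage",
               "Pollinator ethological"))
  expect_equal(unname(roundHalfUp(absoluteContributions(cr), 4)),
               c(0.81, 0.0247, 0, 0.1644))
  expect_equal(roundHalfUp(totalRI(cr), 4), 0.9991)

  # purple-flowered species, sympatric cascade (geographic stage dropped)
  crs <- sequentialContributions(c(0.26, 0.0183, 0.9973),
                                 scenario = "sympatric")
  expect_equal(unname(roundHalfUp(absoluteContributions(crs), 4)),
               c(0.26, 0.0135, 0.7245))

  # allopatric third stage for the purple-flowered species
  cra <- sequentialContributions(c(0.88, 0.26, 0.0183))
  expect_equal(roundHalfUp(absoluteContributions(cra)[[3]], 4), 0.0016)

  # postzygotic pair
  crp <- sequentialContributions(c(0.0244, 0.0350))
  expect_equal(roundHalfUp(totalRI(crp), 4), 0.0585)
})

test_that("a complete first barrier absorbs the whole cascade", {
  cr <- sequentialContributions(c(1, 0.5, 0.9))
  expect_equal(unname(absoluteContributions(cr)), c(1, 0, 0))
  expect_equal(totalRI(cr), 1)
})

test_that("cascade rejects invalid components", {
  expect_error(sequentialContributions(numeric(0)), "at least one")
  expect_error(sequentialContributions(c(0.5, 1.2)), "0, 1")
  expect_error(sequentialContributions(c(-0.1)), "0, 1")
})

test_that("total equals the product identity on random component vectors", {
  set.seed(21)
  for (i in 1:1000) {
    v <- runif(sample(1:8, 1))
    cr <- sequentialContributions(v)
    expect_equal(totalRI(cr), 1 - prod(1 - v), tolerance = 1e-12)
    expect_equal(sum(absoluteContributions(cr)), totalRI(cr),
                 tolerance = 1e-12)
  }
})

test_that("stage order moves absolute but not total contributions", {
  set.seed(22)
  for (i in 1:50) {
    v <- runif(5, 0.05, 0.95)
    p <- sample(5)
    a <- sequentialContributions(v)
    b <- sequentialContributions(v[p])
    expect_equal(totalRI(a), totalRI(b), tolerance = 1e-12)
    expect_false(isTRUE(all.equal(unname(absoluteContributions(a)),
                                  unname(absoluteContributions(b)))))
  }
})

test_that("absolute contributions are bounded by their components", {
  set.seed(23)
  for (i in 1:200) {
    v <- runif(sample(1:6, 1))
    ac <- unname(absoluteContributions(sequentialContributions(v)))
    expect_true(all(ac >= 0 & ac <= v + 1e-15))
  }
})

test_that("adding a positive component never decreases the total", {
  set.seed(24)
  for (i in 1:100) {
    v <- runif(4)
    extra <- runif(1, 0.01, 1)
    expect_gte(totalRI(sequentialContributions(c(v, extra))),
               totalRI(sequentialContributions(v)) - 1e-15)
  }
})

test_that("relative contributions partition the total", {
  set.seed(25)
  for (i in 1:100) {
    v <- runif(5, 0.01, 0.99)
    cr <- sequentialContributions(v)
    rc <- relativeContributions(cr)
    expect_equal(sum(rc), 1, tolerance = 1e-12)
    expect_equal(unname(rc * totalRI(cr)),
                 unname(absoluteContributions(cr)), tolerance = 1e-12)
  }
})

test_that("cascade accepts BarrierComponent lists and keeps stage names", {
  comps <- list(barrierComponent("Geographic", "prezygotic", 0.81),
                barrierComponent("Phenology", "prezygotic", 0.13))
  cr <- sequentialContributions(comps)
  expect_equal(names(absoluteContributions(cr)),
               c("Geographic", "Phenology"))
  expect_equal(roundHalfUp(absoluteContributions(cr)[["Phenology"]], 4),
               0.0247)
})

test_that("the two-species report reproduces the published table layout", {
  fx <- salviaFixture()
  tab <- riTable(fx$components, speciesCols = c("flava", "castanea"))

  pre <- tab[tab$stage_class == "prezygotic", ]
  post <- tab[tab$stage_class == "postzygotic", ]
  expect_equal(pre$AC_flava[pre$stage == "Pollinator ethological"], 0.1644)
  expect_equal(pre$AC_castanea[pre$stage == "Pollinator assemblage"], 0.0016)
  expect_equal(pre$AC_sympatric_castanea[pre$stage == "Pollinator ethological"],
               0.7245)
  expect_equal(pre$AC_flava[pre$stage == "Total"], 0.9991)
  expect_equal(post$AC_flava[post$stage == "Total"], 0.0649)
  expect_equal(post$AC_castanea[post$stage == "Total"], 0.0585)
  expect_equal(post$AC_sympatric_castanea[post$stage == "Total"], 0.0585)
  # geographic stage excluded from the sympatric columns
  expect_true(is.na(pre$AC_sympatric_flava[pre$stage == "Geographic"]))

  # the one reporting-path-sensitive cell: round-last vs sum-of-rounded
  roundLast <- pre$AC_castanea[pre$stage == "Total"]
  tabSR <- riTable(fx$components, speciesCols = c("flava", "castanea"),
                   sumRounded = TRUE)
  sumRounded <- tabSR$AC_castanea[tabSR$stage_class == "prezygotic" &
                                    tabSR$stage == "Total"]
  expect_equal(sumRounded, 0.9997)
  expect_lt(abs(roundLast - 0.9997), 5e-4 + 1e-9)
})

test_that("report omits a stage class absent from the input", {
  fx <- salviaFixture()
  preOnly <- fx$components[fx$components$stage_class == "prezygotic", ]
  tab <- riTable(preOnly, speciesCols = c("flava", "castanea"))
  expect_false("postzygotic" %in% tab$stage_class)
  expect_equal(sum(tab$stage == "Total"), 1L)
})

test_that("report validates its inputs", {
  bad <- data.frame(stage = "x", stage_class = "prezygotic", flava = 1.3,
                    castanea = 0.5)
  expect_error(riTable(bad, speciesCols = c("flava", "castanea")), "0, 1")
  expect_error(riTable(data.frame(stage = "x"), speciesCols = "flava"),
               "columns")
})

test_that("report writes TSV and aligned text faithfully", {
  fx <- salviaFixture()
  tab <- riTable(fx$components, speciesCols = c("flava", "castanea"))
  tsv <- tempfile(fileext = ".tsv")
  writeRITable(tab, tsv)
  back <- read.delim(tsv)
  expect_equal(back$AC_castanea[back$stage == "Total" &
                                  back$stage_class == "postzygotic"], 0.0585)
  txt <- formatRITable(tab)
  expect_match(txt, "Pollinator ethological")
  expect_match(txt, "0.7245", fixed = TRUE)
})
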