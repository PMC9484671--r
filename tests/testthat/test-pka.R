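# Builtin empirical pKa heuristic and the backend contract.

test_that("an isolated amine returns exactly the model pKa", {
  m <- build_ideal_helix(4, "KAAA")
  s <- amine_sites(m)
  eps <- predict_pka(m, s[s$kind == "epsilon", ], react_config())
  expect_equal(eps$pka, 10.5)
  alp <- predict_pka(m, s[s$kind == "alpha", ], react_config())
  expect_equal(alp$pka, 8.0)
})

test_that("a single carboxylate oxygen at 3.5 A shifts a lysine to 10.75", {
  m <- build_ideal_helix(4, "KAAA")
  a <- m$atoms
  nz <- a[a$name == "NZ", ]
  od <- nz
  od$name <- "OD1"; od$elem <- "O"; od$resname <- "ASP"
  od$resno <- 99L; od$serial <- max(a$serial) + 1L
  od$x <- nz$x + 3.5
  m2 <- aminereact:::new_structure(rbind(a, od))
  s <- amine_sites(m2)
  r <- predict_pka(m2, s[s$kind == "epsilon", ], react_config())
  expect_equal(r$pka, 10.5 + 0.5 * (1 - 3.5 / 7))
  expect_equal(unname(r$terms[["charge"]]), 0.25)
})

test_that("terms are additive and shifts are monotone in charge sign", {
  m <- build_ideal_helix(4, "KAAA")
  base <- m$atoms
  nz <- base[base$name == "NZ", ]
  put <- function(name, resname, elem, dx) {
    extra <- nz
    extra$name <- name; extra$resname <- resname; extra$elem <- elem
    extra$resno <- 98L; extra$serial <- max(base$serial) + 1L
    extra$x <- nz$x + dx
    aminereact:::new_structure(rbind(base, extra))
  }
  cfg <- react_config()
  pk0 <- 10.5
  for (d in c(2, 4, 6.5)) {
    manion <- put("OE1", "GLU", "O", d)
    s <- amine_sites(manion)
    r <- predict_pka(manion, s[s$kind == "epsilon", ], cfg)
    expect_gte(r$pka, pk0)                 # anion never decreases
    expect_equal(r$pka, sum(r$terms))      # exact additivity
    mcat <- put("CZ", "ARG", "C", d)
    s2 <- amine_sites(mcat)
    r2 <- predict_pka(mcat, s2[s2$kind == "epsilon", ], cfg)
    expect_lte(r2$pka, pk0)                # cation never increases
    expect_equal(r2$pka, sum(r2$terms))
  }
  # beyond the 7 A interaction radius: no shift
  far <- put("OE1", "GLU", "O", 7.5)
  sf <- amine_sites(far)
  expect_equal(predict_pka(far, sf[sf$kind == "epsilon", ], cfg)$pka, 10.5)
})

test_that("burial term counts heavy neighbours above the baseline", {
  # a dense dummy shell of >280 heavy atoms within 9 A of the amine
  m <- build_ideal_helix(4, "KAAA")
  a <- m$atoms
  nz <- unlist(a[a$name == "NZ", c("x", "y", "z")])
  set.seed(5)
  npts <- 320
  u <- matrix(rnorm(3 * npts), ncol = 3)
  u <- u / sqrt(rowSums(u^2)) * runif(npts, 7.2, 8.8)
  extra <- data.frame(serial = max(a$serial) + seq_len(npts),
                      name = "X", elem = "C", resname = "SPH",
                      chain = "A", resno = 500L + seq_len(npts),
                      insert = "",
                      x = nz[1] + u[, 1], y = nz[2] + u[, 2],
                      z = nz[3] + u[, 3], het = FALSE,
                      stringsAsFactors = FALSE)
  m2 <- aminereact:::new_structure(rbind(a, extra))
  s <- amine_sites(m2)
  r <- predict_pka(m2, s[s$kind == "epsilon", ], react_config())
  n_heavy <- sum(sqrt((m2$atoms$x - nz[1])^2 + (m2$atoms$y - nz[2])^2 +
                        (m2$atoms$z - nz[3])^2) <= 9 &
                   m2$atoms$elem != "H") - 1
  expect_equal(unname(r$terms[["desolvation"]]),
               0.01 * max(0, n_heavy - 280))
  expect_gt(r$pka, 10.5)
})

test_that("backend contract: builtin resolves, unregistered external fails fast, results are deterministic", {
  m <- build_ideal_helix(4, "KAAA")
  s <- amine_sites(m)
  expect_error(react_config(pka_backend = "propka9"), "unknown")
  expect_error(pka_backend("external"), "configuration error")
  r1 <- predict_pka(m, s[1, ], react_config())
  r2 <- predict_pka(m, s[1, ], react_config())
  expect_identical(r1$pka, r2$pka)
  # a registered external backend is dispatched and labelled
  pka_backend("external", function(model, site, config)
    list(pka = 9.99, terms = c(model = 9.99)))
  on.exit(rm(list = "external", envir = aminereact:::pka_backends))
  cfg <- react_config(pka_backend = "external")
  rx <- predict_pka(m, s[1, ], cfg)
  expect_equal(rx$pka, 9.99)
  expect_equal(rx$backend, "external")
  # implausible backend output is rejected
  pka_backend("external", function(model, site, config)
    list(pka = 42, terms = c(model = 42)))
  expect_error(predict_pka(m, s[1, ], cfg), "implausible")
})

test_that("a missing amine nitrogen is reported by site id", {
  m <- build_ideal_helix(4, "KAAA")
  s <- amine_sites(m)
  bad <- s[s$kind == "epsilon", ]
  bad$n_idx <- 2L   # points at a CA, not the NZ
  expect_error(predict_pka(m, bad, react_config()), "amine nitrogen missing")
})
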