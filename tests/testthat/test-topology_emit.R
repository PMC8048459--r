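make_abcd <- function() {
  atoms <- atom_table(c("A", "B", "C", "D"), element = rep("C", 4))
  atoms$charge <- c(0.1, -0.1, 0.2, -0.2)
  molecule_geometry(atoms, rbind(c(0, 0, 0), c(0.15, 0, 0),
                                 c(0.30, 0, 0), c(0.45, 0, 0)))
}

test_that("a 4-atom chain splits at the boundary into the expected halves", {
  geom <- make_abcd()
  sp <- split_crosslink(geom, boundary = list(c("B", "C")))
  expect_setequal(sp$residue_a$atoms$name, c("A", "B"))
  expect_setequal(sp$residue_b$atoms$name, c("C", "D"))
  expect_equal(sp$connections$atom_a, "B")
  expect_equal(sp$connections$atom_b, "C")
  expect_equal(sp$connections$b0, 0.15, tolerance = 1e-12)
  # split + caps partition the atom set exactly
  expect_setequal(c(sp$residue_a$atoms$name, sp$residue_b$atoms$name),
                  geom$atoms$name)
})

test_that("invalid boundaries are rejected with diagnostics", {
  geom <- make_abcd()
  expect_error(split_crosslink(geom, boundary = list(c("A", "D"))),
               "not an existing bond")
  # cutting an interior bond of a cycle yields one component
  atoms <- atom_table(c("A", "B", "C"), element = rep("C", 3))
  tri <- molecule_geometry(atoms, rbind(c(0, 0, 0), c(0.15, 0, 0),
                                        c(0.075, 0.13, 0)))
  expect_error(split_crosslink(tri, boundary = list(c("A", "B"))),
               "expected 2")
})

test_that("cross-link fixtures split along their generating partition", {
  for (kind in c("DOGDIC-like", "GODIC-like", "MODIC-like")) {
    fx <- make_crosslink_fixture(kind)
    sp <- split_crosslink(fx$geometry, fx$boundary, bonds = fx$bonds,
                          caps = fx$caps)
    expect_setequal(sp$residue_a$atoms$name, fx$truth$side_a)
    expect_setequal(sp$residue_b$atoms$name, fx$truth$side_b)
    # caps are excluded from both residues
    expect_false(any(fx$caps %in% c(sp$residue_a$atoms$name,
                                    sp$residue_b$atoms$name)))
    # the lysine-derived half holds the backbone amide, the other the ring
    expect_true(all(c("N", "HN") %in% sp$residue_a$atoms$name))
    expect_true(all(c("ND4", "ND5", "ND6") %in% sp$residue_b$atoms$name))
  }
})

test_that("the DOGDIC-like fixture resolves every default donor/acceptor name", {
  fx <- make_crosslink_fixture("DOGDIC-like")
  nms <- fx$geometry$atoms$name
  expect_true(all(c("HD5", "HD6", "HN") %in% nms))
  expect_true(all(c("N", "ND2", "ND4", "ND5", "ND6", "OD1", "OD2", "OD3",
                    "OD4", "OD5") %in% nms))
})

test_that("net-charge validation passes, fails and errors as specified", {
  fx <- make_crosslink_fixture("DOGDIC-like")
  sp <- split_crosslink(fx$geometry, fx$boundary, bonds = fx$bonds,
                        caps = fx$caps)
  conn <- sp$connections; conn$k_b <- 2.5e5
  top <- crosslink_topology(sp$residue_a, sp$residue_b, conn)
  chk <- check_net_charge(top)
  expect_true(chk$pass)
  expect_lt(abs(chk$total_charge), 1e-12)

  biased <- top
  biased$residue_a$atoms$charge[1] <- biased$residue_a$atoms$charge[1] + 0.001
  chk2 <- check_net_charge(biased)
  expect_false(chk2$pass)
  expect_equal(chk2$total_charge, 0.001, tolerance = 1e-9)

  missing <- top
  missing$residue_b$atoms$charge[2] <- NA
  expect_error(check_net_charge(missing), missing$residue_b$atoms$name[2])
})

test_that("residue entries round-trip and are byte-stable", {
  fx <- make_crosslink_fixture("DOGDIC-like")
  sp <- split_crosslink(fx$geometry, fx$boundary, bonds = fx$bonds,
                        caps = fx$caps)
  conn <- sp$connections; conn$k_b <- 2.5e5
  top <- crosslink_topology(sp$residue_a, sp$residue_b, conn)
  p1 <- withr::local_tempfile(fileext = ".rtp")
  p2 <- withr::local_tempfile(fileext = ".rtp")
  write_residue_entries(top, p1)
  write_residue_entries(top, p2)
  expect_identical(readLines(p1), readLines(p2))
  expect_equal(sum(grepl("^\\[ ", readLines(p1))), 2L)

  back <- read_residue_entries(p1)
  expect_equal(back[[top$residue_a$name]]$atoms$name, top$residue_a$atoms$name)
  expect_equal(back[[top$residue_a$name]]$atoms$charge,
               round(top$residue_a$atoms$charge, 6), tolerance = 1e-9)
  expect_equal(back[[top$residue_b$name]]$bonds, top$residue_b$bonds)
})

test_that("empty residues are refused", {
  expect_error(residue_template("X", data.frame(name = character(),
                                                type = character(),
                                                charge = numeric())),
               "empty residue")
})

test_that("specbond records echo derived lengths and enforce preconditions", {
  geom <- make_abcd()
  sp <- split_crosslink(geom, boundary = list(c("B", "C")))
  conn <- sp$connections
  conn$b0 <- 0.153
  top <- crosslink_topology(sp$residue_a, sp$residue_b, conn)
  path <- withr::local_tempfile()
  write_specbond(top, path)
  lines <- readLines(path)
  expect_match(lines[2], "0.153")
  back <- read_specbond(path)
  expect_equal(back$b0, 0.153)
  expect_equal(back$atom_a, "B")

  top0 <- top
  top0$connection_bonds <- conn[0, ]
  expect_error(write_specbond(top0, path), "no connection bonds")
  top_na <- top
  top_na$connection_bonds$b0 <- NA
  expect_error(write_specbond(top_na, path), "without a derived b0")
})

test_that("bonded parameter tables round-trip to full precision", {
  c5 <- make_toy_molecule(recipe_chain5())
  ps <- derive_all(c5$hessian, c5$geometry,
                   lapply(1:4, function(i) c(i, i + 1L)),
                   lapply(1:3, function(i) c(i, i + 1L, i + 2L)))
  path <- withr::local_tempfile(fileext = ".itp")
  write_bonded_parameters(ps, path)
  back <- read_bonded_parameters(path)
  ord <- order(ps$bonds$name_i, ps$bonds$name_j)
  expect_equal(back$bonds$b0, ps$bonds$b0[ord], tolerance = 1e-10)
  orda <- order(ps$angles$name_i, ps$angles$name_j, ps$angles$name_k)
  expect_equal(back$angles$theta0, ps$angles$theta0[orda], tolerance = 1e-8)
  expect_equal(back$angles$k_theta, ps$angles$k_theta[orda], tolerance = 1e-6)

  empty <- derive_all(c5$hessian, c5$geometry, list(), list())
  expect_warning(write_bonded_parameters(empty, path), "empty parameter set")
  expect_equal(readLines(path), c("[ bondtypes ]", "[ angletypes ]"))
})

test_that("bond-graph inference finds chain bonds at covalent distances", {
  geom <- make_abcd()
  b <- infer_bonds(geom)
  expect_equal(nrow(b), 3L)
  expect_equal(b$i, 1:3)
  expect_equal(b$j, 2:4)
})
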