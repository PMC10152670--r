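# two isolated carbons at a chosen distance
two_carbons <- function(d) {
  data.frame(serial = 1:2, name = c("C1", "C2"), altloc = "",
             resname = c("LIG", "LIG"), chain = c("X", "Y"), resno = 1:2,
             x = c(0, d), y = 0, z = 0, occupancy = 1, bfactor = 0,
             element = "C", stringsAsFactors = FALSE)
}

test_that("contact and clash thresholds behave at their boundaries", {
  # carbons: r = 1.70 each, sum 3.40
  m <- two_carbons(3.40)
  rep_ <- vdw_contacts(m, 1, 2)
  expect_equal(nrow(rep_), 1)
  expect_equal(rep_$gap, 0)
  expect_equal(rep_$classification, "contact")
  # 4.00 > 3.40 + 0.5: no contact
  expect_equal(nrow(vdw_contacts(two_carbons(4.00), 1, 2)), 0)
  # 2.90: overlap 0.50 > 0.4 -> clash
  cl <- detect_clashes(two_carbons(2.90), 1, 2)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 0.5)
  # 3.10: overlap 0.30 -> no clash
  expect_equal(nrow(detect_clashes(two_carbons(3.10), 1, 2)), 0)
  # degenerate selections error
  expect_error(vdw_contacts(m, integer(0), 2), "empty")
  expect_error(vdw_contacts(m, 1:2, 2), "disjoint")
})

test_that("contact and clash relations are symmetric in the selections", {
  fx <- build_geometry_fixture(methylated = TRUE, n_models = 1)
  m <- fx$models[[1]]
  a <- select_atoms(m, chain = "A", resno = 4)
  b <- select_atoms(m, chain = "B")
  ab <- vdw_contacts(m, a, b)
  ba <- vdw_contacts(m, b, a)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$atom_a, ab$atom_b), paste(ba$atom_b, ba$atom_a))
  expect_equal(sort(ab$distance), sort(ba$distance))
})

test_that("clashes are a subset of contacts under the default thresholds", {
  fx <- build_geometry_fixture(methylated = TRUE, n_models = 1)
  m <- fx$models[[1]]
  a <- select_atoms(m, chain = "A")
  b <- select_atoms(m, chain = "B")
  contacts <- vdw_contacts(m, a, b)
  clashes <- detect_clashes(m, a, b)
  expect_true(all(paste(clashes$atom_a, clashes$atom_b) %in%
                    paste(contacts$atom_a, contacts$atom_b)))
})

test_that("methylation adds one in-plane carbon with ideal geometry", {
  fx <- build_geometry_fixture(n_models = 1)
  m <- fx$models[[1]]
  mm <- methylate_cytosine(m, "A", 4)
  expect_equal(nrow(mm), nrow(m) + 1)
  get <- function(model, nm) {
    i <- select_atoms(model, chain = "A", resno = 4, name = nm)
    as.numeric(model[i, c("x", "y", "z")])
  }
  c5m <- get(mm, "C5M")
  c5 <- get(mm, "C5"); c4 <- get(mm, "C4"); c6 <- get(mm, "C6")
  # bond length 1.50 A by construction
  expect_equal(sqrt(sum((c5m - c5)^2)), 1.50, tolerance = 1e-6)
  # in the base plane
  base_sel <- select_atoms(mm, chain = "A", resno = 4)
  expect_lt(max(abs(plane_residuals(mm, base_sel))), 1e-3)
  # external bisector: equal angles to C4 and C6
  ang <- function(a, b, c) {
    u <- a - b; v <- c - b
    acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
  }
  expect_equal(ang(c4, c5, c5m), ang(c6, c5, c5m), tolerance = 1e-9)
  # brute-force oracle: the in-plane unit vector with equal angles to both
  # ring neighbours and maximal distance from the ring is the bisector
  u1 <- (c4 - c5) / sqrt(sum((c4 - c5)^2))
  u2 <- (c6 - c5) / sqrt(sum((c6 - c5)^2))
  b <- -(u1 + u2) / sqrt(sum((u1 + u2)^2))
  expect_equal(c5m, c5 + 1.5 * b, tolerance = 1e-9)

  # guard rails
  expect_error(methylate_cytosine(mm, "A", 4), "already carries")
  expect_error(methylate_cytosine(m, "A", 104), "not a cytosine")
  expect_error(methylate_cytosine(m, "A", 999), "no residue")
  broken <- m[m$name != "C6" | m$resno != 4, ]
  expect_error(methylate_cytosine(broken, "A", 4), "C6 missing")
})

test_that("unmethylated fixture touches the tyrosine without clashing", {
  fx <- build_geometry_fixture(methylated = FALSE)
  for (m in fx$models) {
    base <- select_atoms(m, chain = "A", resno = 4)
    tyr <- select_atoms(m, chain = "B", resname = "TYR")
    contacts <- vdw_contacts(m, base, tyr)
    clashes <- detect_clashes(m, base, tyr)
    expect_gte(nrow(contacts), 1)
    expect_equal(nrow(clashes), 0)
    # exhaustive distance enumeration agrees
    oracle <- oracle_pair_classes(m, base, tyr)
    expect_equal(nrow(contacts), oracle$contacts)
    expect_equal(oracle$clashes, 0)
  }
  base <- select_atoms(fx$models[[1]], chain = "A", resno = 4)
  tyr <- select_atoms(fx$models[[1]], chain = "B")
  expect_equal(contact_persistence(fx, base, tyr), 1.0)
})

test_that("the 5-methyl group converts the contact into a steric clash", {
  fx <- build_geometry_fixture(methylated = TRUE)
  for (m in fx$models) {
    base <- select_atoms(m, chain = "A", resno = 4)
    tyr <- select_atoms(m, chain = "B", resname = "TYR")
    clashes <- detect_clashes(m, base, tyr)
    expect_gte(nrow(clashes), 1)
    expect_true(any(grepl("C5M", clashes$atom_a)))
    oracle <- oracle_pair_classes(m, base, tyr)
    expect_equal(nrow(clashes), oracle$clashes)
  }
  m1 <- fx$models[[1]]
  expect_equal(contact_persistence(fx, select_atoms(m1, chain = "A", resno = 4),
                                   select_atoms(m1, chain = "B"), mode = "clash"),
               1.0)
})

test_that("base-pair atoms are coplanar in every model", {
  for (methylated in c(FALSE, TRUE)) {
    fx <- build_geometry_fixture(methylated = methylated)
    for (m in fx$models) {
      dna <- select_atoms(m, chain = "A")
      expect_lt(max(abs(plane_residuals(m, dna))), 1e-3)
    }
  }
})

test_that("persistence counts the fraction of contacting models", {
  fx <- build_geometry_fixture(n_models = 1)
  near <- fx$models[[1]]
  far <- near
  moved <- near$chain == "B"
  far$x[moved] <- far$x[moved] + 50  # move the tyrosine 50 A away
  ens <- structure_ensemble(c(rep(list(near), 7), rep(list(far), 3)))
  base <- select_atoms(near, chain = "A", resno = 4)
  tyr <- select_atoms(near, chain = "B")
  expect_equal(contact_persistence(ens, base, tyr), 0.7)
  all_far <- structure_ensemble(rep(list(far), 10))
  expect_equal(contact_persistence(all_far, base, tyr), 0.0)

  # topology mismatch is an error
  mixed <- structure_ensemble(list(near, methylate_cytosine(near, "A", 4)))
  expect_false(mixed$shared_topology)
  expect_error(contact_persistence(mixed, base, tyr), "shared topology")
})

test_that("united-atom methyl radius is configurable", {
  fx <- build_geometry_fixture(methylated = TRUE, n_models = 1)
  m <- fx$models[[1]]
  base <- select_atoms(m, chain = "A", resno = 4)
  tyr <- select_atoms(m, chain = "B")
  default <- detect_clashes(m, base, tyr)
  explicit <- detect_clashes(m, base, tyr, vdw = vdw_table(methyl_radius = 1.70))
  # smaller methyl radius can only reduce the clash count, never grow it
  expect_lte(nrow(explicit), nrow(default))
  expect_gte(nrow(explicit), 1)  # still clashes: C5M sits 2.1 A from the ring
})
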