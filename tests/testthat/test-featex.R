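test_that("surface integrator matches analytic sphere areas", {
  # isolated atom: full sphere of radius vdW + probe
  at1 <- data.frame(type = "ATOM", eleno = 1L, elety = "CA", resid = "ALA",
                    chain = "A", resno = 1L, x = 0, y = 0, z = 0, o = 1, b = 0,
                    element = "C", stringsAsFactors = FALSE)
  expect_equal(atom_sasa(at1), 4 * pi * (1.70 + 1.4)^2, tolerance = 1e-9)
  # two-sphere union vs the closed-form spherical-cap oracle
  d <- 2.5
  at2 <- rbind(at1, within(at1, { x <- d; eleno <- 2L }))
  R <- 1.70 + 1.4
  h <- R - (d^2) / (2 * d)  # cap height for equal radii
  analytic <- 2 * (4 * pi * R^2 - 2 * pi * R * h)
  expect_equal(sum(atom_sasa(at2)), analytic, tolerance = 0.01 * analytic)
  # independent Monte-Carlo integrator at high sample count
  set.seed(1)
  n_mc <- 40000
  mc_pts <- matrix(stats::rnorm(3 * n_mc), ncol = 3)
  mc_pts <- mc_pts / sqrt(rowSums(mc_pts^2))
  mc_area <- vapply(1:2, function(i) {
    centre <- c(if (i == 1) 0 else d, 0, 0)
    surf <- sweep(mc_pts * R, 2, centre, "+")
    other <- c(if (i == 1) d else 0, 0, 0)
    frac <- mean(sqrt(rowSums(sweep(surf, 2, other)^2)) >= R)
    4 * pi * R^2 * frac
  }, numeric(1))
  expect_equal(sum(atom_sasa(at2)), sum(mc_area), tolerance = 0.02 * sum(mc_area))
})

test_that("surface features vanish for an identical pair and flag buried residues", {
  fx <- toy_fixture()
  sf <- surface_accessibility_features(fx$wt, fx$wt, fx$site,
                                       fx$toy$hbond_resno, n_points = 240)
  expect_equal(sf$site_sasa_absdiff, 0)
  expect_equal(sf$res_sasa_absdiff, 0)
  expect_equal(sf$rsa_absdiff, 0)
  expect_gt(sf$site_sasa_wt, 0)
  expect_true(sf$rsa_wt >= 0 && sf$rsa_wt <= 1.5)
  # a residue packed inside a dense cage has RSA ~ 0
  cage <- expand.grid(x = seq(-4, 4, 2), y = seq(-4, 4, 2), z = seq(-4, 4, 2))
  rows <- data.frame(type = "ATOM", eleno = seq_len(nrow(cage) + 1),
                     elety = c("CA", paste0("C", seq_len(nrow(cage)))),
                     resid = "ALA", chain = "A",
                     resno = c(1L, rep(2L, nrow(cage))),
                     x = c(0, cage$x), y = c(0, cage$y), z = c(0, cage$z),
                     o = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  rows <- rows[c(TRUE, !(cage$x == 0 & cage$y == 0 & cage$z == 0)), ]
  rows$eleno <- seq_len(nrow(rows))
  lig <- data.frame(type = "HETATM", eleno = nrow(rows) + 1L, elety = "C1",
                    resid = "LIG", chain = "A", resno = 99L, x = 30, y = 0,
                    z = 0, o = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  buried <- complex_model(rbind(rows, lig), "LIG")
  expect_lt(residue_sasa(buried, 1, n_points = 240) / 129, 0.05)
})

test_that("half-sphere exposure partitions CA neighbours by the CB axis", {
  # hand geometry: residue at origin with CB along +z; neighbours above/below
  mk_res <- function(resno, ca, with_cb = FALSE) {
    at <- data.frame(type = "ATOM", eleno = 0L,
                     elety = c("N", "CA", "C"), resid = "ALA", chain = "A",
                     resno = resno,
                     x = ca[1] + c(-1.2, 0, 1.2), y = ca[2] + c(0.5, 0, 0.5),
                     z = ca[3], o = 1, b = 0, element = c("N", "C", "C"),
                     stringsAsFactors = FALSE)
    if (with_cb) at <- rbind(at, within(at[2, ], {
      elety <- "CB"; z <- z + 1.5; element <- "C" }))
    at
  }
  at <- rbind(mk_res(1, c(0, 0, 0), with_cb = TRUE),
              mk_res(2, c(3, 0, 5)),    # above: +z side
              mk_res(3, c(-3, 0, -5)),  # below
              mk_res(4, c(0, 40, 0)))   # outside the 13 A radius
  lig <- data.frame(type = "HETATM", eleno = 0L, elety = "C1", resid = "LIG",
                    chain = "A", resno = 99L, x = 0, y = -30, z = 0, o = 1,
                    b = 0, element = "C", stringsAsFactors = FALSE)
  at <- rbind(at, lig); at$eleno <- seq_len(nrow(at))
  cm <- complex_model(at, "LIG")
  hse <- half_sphere_exposure(cm, 1)
  expect_equal(unname(hse), c(1, 1))
  # isolated residue
  solo <- complex_model(rbind(mk_res(1, c(0, 0, 0), TRUE), lig), "LIG")
  expect_equal(unname(half_sphere_exposure(solo, 1)), c(0, 0))
  # glycine pseudo-CB is finite
  fx <- toy_fixture()
  g <- Filter(function(x) x$alt_aa == "G", fx$mutants)[[1]]
  mt <- build_mutant_model(fx$wt, g)$structure
  expect_false(anyNA(half_sphere_exposure(mt, g$protein_position)))
})

test_that("hydrogen-bond detector flips at 3.2 A and requires polar atoms", {
  fx <- toy_fixture()
  hb <- load_complex(fx$toy$boundary$hbond, "LIG")
  expect_true(hydrogen_bond_features(hb, 1)$present)    # 3.19
  expect_false(hydrogen_bond_features(hb, 2)$present)   # 3.21
  expect_false(hydrogen_bond_features(hb, 3)$present)   # C-C at 2.9
  expect_equal(hydrogen_bond_features(hb, 1)$distance, 3.19, tolerance = 1e-2)
  # the closest candidate pair is the one reported
  got <- hydrogen_bond_features(fx$wt, fx$toy$hbond_resno)
  res <- fx$wt$protein[fx$wt$protein$resno == fx$toy$hbond_resno, ]
  res <- res[res$element %in% c("N", "O", "F"), ]
  lig <- fx$wt$ligand[fx$wt$ligand$element %in% c("N", "O", "F"), ]
  dmin <- min(resmutscan:::cross_dist(as.matrix(res[, c("x", "y", "z")]),
                                      as.matrix(lig[, c("x", "y", "z")])))
  expect_equal(got$distance, dmin, tolerance = 1e-9)
})

test_that("environment encodings bin neighbours into annular shells", {
  fx <- toy_fixture()
  m <- fx$mutants[[1]]
  env <- environment_encodings(fx$wt, m$protein_position, m$ref_aa, m$alt_aa)
  expect_equal(dim(env$shells), c(6, 20))
  expect_true(all(env$shells %in% 0:1))
  expect_equal(sum(env$mutation), 0)
  expect_equal(unname(env$mutation[m$ref_aa]), -1)
  expect_equal(unname(env$mutation[m$alt_aa]), 1)
  # a neighbour whose nearest atom is at 2.5 A occupies shell (2,3] only
  at <- rbind(
    data.frame(type = "ATOM", eleno = 0L, elety = c("N", "CA", "C"),
               resid = "ALA", chain = "A", resno = 1L,
               x = c(-1.2, 0, 1.2), y = c(0.5, 0, 0.5), z = 0,
               o = 1, b = 0, element = c("N", "C", "C"),
               stringsAsFactors = FALSE),
    data.frame(type = "ATOM", eleno = 0L, elety = "CA", resid = "LEU",
               chain = "A", resno = 2L, x = 0, y = 2.5, z = 0, o = 1, b = 0,
               element = "C", stringsAsFactors = FALSE),
    data.frame(type = "HETATM", eleno = 0L, elety = "C1", resid = "LIG",
               chain = "A", resno = 9L, x = 0, y = -30, z = 0, o = 1, b = 0,
               element = "C", stringsAsFactors = FALSE))
  at$eleno <- seq_len(nrow(at))
  cm <- complex_model(at, "LIG")
  env2 <- environment_encodings(cm, 1, "A", "G")
  expect_equal(unname(env2$shells[3, "L"]), 1)
  expect_equal(sum(env2$shells[-3, "L"]), 0)
  # isolated residue: all shells empty
  solo <- complex_model(at[-4, ], "LIG")
  env3 <- environment_encodings(solo, 1, "A", "G")
  expect_equal(sum(env3$shells), 0)
})

test_that("secondary-structure assigner recovers canonical geometries", {
  # backbone built from internal coordinates (NeRF placement) at prescribed
  # phi/psi; bond lengths/angles are the standard peptide values
  nerf <- function(A, B, C, r, theta, chi) {
    th <- theta * pi / 180; ph <- chi * pi / 180
    bc <- resmutscan:::vunit(C - B)
    n <- resmutscan:::vunit(resmutscan:::vcross(B - A, bc))
    m <- resmutscan:::vcross(n, bc)
    d <- r * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
    C + d[1] * bc + d[2] * m + d[3] * n
  }
  torsion_chain <- function(n_res, phi, psi) {
    N <- c(0, 0, 0); CA <- c(1.458, 0, 0)
    C <- nerf(c(-1, 1, 0), N, CA, 1.525, 111.2, -60)
    atoms <- list(list(N = N, CA = CA, C = C))
    for (i in 2:n_res) {
      Nn <- nerf(atoms[[i - 1]]$N, atoms[[i - 1]]$CA, atoms[[i - 1]]$C,
                 1.329, 116.2, psi)
      CAn <- nerf(atoms[[i - 1]]$CA, atoms[[i - 1]]$C, Nn, 1.458, 121.7, 180)
      Cn <- nerf(atoms[[i - 1]]$C, Nn, CAn, 1.525, 111.2, phi)
      atoms[[i]] <- list(N = Nn, CA = CAn, C = Cn)
    }
    rows <- do.call(rbind, lapply(seq_len(n_res), function(i) {
      xyz <- rbind(atoms[[i]]$N, atoms[[i]]$CA, atoms[[i]]$C)
      data.frame(type = "ATOM", eleno = 0L, elety = c("N", "CA", "C"),
                 resid = "ALA", chain = "A", resno = i,
                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
                 element = c("N", "C", "C"), stringsAsFactors = FALSE)
    }))
    lig <- data.frame(type = "HETATM", eleno = 0L, elety = "C1",
                      resid = "LIG", chain = "A", resno = 99L, x = 50, y = 0,
                      z = 0, o = 1, b = 0, element = "C",
                      stringsAsFactors = FALSE)
    at <- rbind(rows, lig)
    at$eleno <- seq_len(nrow(at))
    complex_model(at, "LIG")
  }
  helix <- torsion_chain(6, phi = -57, psi = -47)
  ss_h <- secondary_structure(helix, 3)
  expect_true(ss_h$known)
  expect_equal(ss_h$phi, -57, tolerance = 0.01)
  expect_equal(ss_h$psi, -47, tolerance = 0.01)
  expect_equal(ss_h$label, "H")
  strand <- torsion_chain(6, phi = -135, psi = 135)
  ss_e <- secondary_structure(strand, 3)
  expect_equal(ss_e$label, "E")
  # terminal / incomplete windows degrade to coil + unknown
  fx <- toy_fixture()
  ss_end <- secondary_structure(fx$wt, 1)
  expect_equal(ss_end$label, "C")
  expect_false(ss_end$known)
})

test_that("stability surrogate signs categories and tolerates backend failure", {
  fx <- toy_fixture()
  m <- fx$mutants[[2]]
  st <- stability_change(fx$wt, m, rsa_wt = 0.3)
  expect_true(st$category %in% c("STABLE", "UNSTABLE"))
  expect_equal(st$category, if (st$ddG >= 0) "STABLE" else "UNSTABLE")
  # explicit backends pin the sign rule
  st_neg <- stability_change(fx$wt, m, backend = function(...) -1.3)
  expect_equal(st_neg$category, "UNSTABLE")
  st_pos <- stability_change(fx$wt, m, backend = function(...) 0.2)
  expect_equal(st_pos$category, "STABLE")
  st_na <- stability_change(fx$wt, m, backend = function(...) NA_real_)
  expect_equal(st_na$category, "UNKNOWN")
  expect_true(is.na(st_na$ddG))
})

test_that("conservation score equals the all-pairs BLOSUM62 average", {
  expect_equal(conservation_score(c("L", "L", "L"), 1), 4)  # BLOSUM62(L,L)
  expect_equal(conservation_score(c("L", "M"), 1), 2)       # BLOSUM62(L,M)
  set.seed(8)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  B <- get("BLOSUM62", envir = environment())
  for (rep in 1:10) {
    col <- sample(resmutscan:::AA1, 5, replace = TRUE)
    tot <- 0; cnt <- 0
    for (i in 1:4) for (j in (i + 1):5) { tot <- tot + B[col[i], col[j]]; cnt <- cnt + 1 }
    expect_equal(conservation_score(col, 1), tot / cnt)
  }
  expect_true(is.na(conservation_score(c("-", "-"), 1)))
  expect_error(conservation_score(c("LL", "L-"), 3), "width")
})

test_that("alignment RMSD is superposition-invariant and refinement rejects outliers", {
  fx <- toy_fixture()
  r0 <- alignment_rmsd(fx$wt, fx$wt)
  expect_equal(unname(r0), c(0, 0), tolerance = 1e-6)
  # rigid rotation + translation of itself
  rot <- resmutscan:::rotation_matrix(c(1, 2, 3), 73)
  moved <- transform_complex(fx$wt, rot, c(5, -3, 9))
  r1 <- alignment_rmsd(fx$wt, moved)
  expect_equal(unname(r1), c(0, 0), tolerance = 1e-6)
  # cross-check the raw superposition against the bio3d implementation
  m <- Filter(function(x) x$alt_aa != "G", fx$mutants)[[1]]
  mt <- transform_complex(build_mutant_model(fx$wt, m)$structure, rot, c(1, 1, 1))
  got <- alignment_rmsd(fx$wt, mt)
  a <- resmutscan:::heavy(fx$wt$protein); b <- resmutscan:::heavy(mt$protein)
  ka <- paste(a$chain, a$resno, a$elety); kb <- paste(b$chain, b$resno, b$elety)
  shared <- intersect(ka, kb)
  xa <- as.numeric(t(as.matrix(a[match(shared, ka), c("x", "y", "z")])))
  xb <- as.numeric(t(as.matrix(b[match(shared, kb), c("x", "y", "z")])))
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = xa, mobile = xb))
  expect_equal(unname(got["raw"]), bio3d::rmsd(xa, fitted), tolerance = 1e-4)
  # one displaced atom among many: refinement drops it
  disp <- fx$wt
  i <- which(disp$protein$elety == "CB")[1]
  disp$protein$x[i] <- disp$protein$x[i] + 4
  r2 <- alignment_rmsd(fx$wt, disp)
  expect_lt(r2["refined"], r2["raw"])
  expect_lt(r2["refined"], 0.05)
})

test_that("ligand distance features reduce to simple arithmetic", {
  mk <- function(lig_xyz) {
    prot <- data.frame(type = "ATOM", eleno = 0L, elety = c("N", "CA", "C"),
                       resid = "ALA", chain = "A", resno = 1L,
                       x = c(-1.2, 0, 1.2), y = c(0.5, 0, 0.5), z = 0,
                       o = 1, b = 0, element = c("N", "C", "C"),
                       stringsAsFactors = FALSE)
    lig <- data.frame(type = "HETATM", eleno = 0L,
                      elety = paste0("C", seq_len(nrow(lig_xyz))),
                      resid = "LIG", chain = "A", resno = 9L,
                      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
                      o = 1, b = 0, element = "C", stringsAsFactors = FALSE)
    at <- rbind(prot, lig); at$eleno <- seq_len(nrow(at))
    complex_model(at, "LIG")
  }
  expect_equal(unname(ligand_distance_features(mk(matrix(c(5, 0, 0), 1)), 1)),
               c(5, 5, 5))
  expect_equal(unname(ligand_distance_features(
    mk(matrix(c(4, 0, 0, 8, 0, 0), 2, byrow = TRUE)), 1)), c(4, 8, 6))
  set.seed(3)
  xyz <- matrix(stats::rnorm(15, sd = 5), ncol = 3)
  d <- sqrt(rowSums(xyz^2))
  expect_equal(unname(ligand_distance_features(mk(xyz), 1)),
               c(min(d), max(d), mean(d)))
})

test_that("charge and hydrophobicity encodings follow the bundled scales", {
  dk <- charge_hydrophobicity_features("D", "K")
  expect_equal(unname(dk$charge["D"]), -1)
  expect_equal(unname(dk$charge["K"]), 1)
  expect_equal(sum(dk$charge != 0), 2)
  il <- charge_hydrophobicity_features("I", "L")
  expect_equal(il$dhydro, 3.8 - 4.5)
  expect_equal(sum(il$charge), 0)
})

test_that("salt-bridge and disulfide detectors flip at their windows", {
  fx <- toy_fixture()
  sb <- load_complex(fx$toy$boundary$saltbridge, "LIG")
  expect_equal(salt_bridge_features(sb, 1)$pp_count, 1)   # 3.9
  expect_equal(salt_bridge_features(sb, 2)$pp_count, 1)   # partner side
  expect_equal(salt_bridge_features(sb, 3)$pp_count, 0)   # 4.1
  di <- load_complex(fx$toy$boundary$disulfide, "LIG")
  expect_true(disulfide_check(di, 1))   # 2.0
  expect_true(disulfide_check(di, 2))
  expect_false(disulfide_check(di, 3))  # 2.3
  # non-cysteine is never bonded regardless of geometry
  expect_false(disulfide_check(sb, 1))
})

test_that("interaction fingerprint detects constructed geometries", {
  fx <- toy_fixture()
  # water bridge scripted into the main complex
  fp <- ligand_interaction_fingerprint(fx$wt, fx$toy$hbond_resno)
  expect_true(fp$water_bridge$present)
  # stacked benzene over a phenylalanine ring at 4.0 A
  phe_pos <- which(fx$toy$sequence == "F")
  phe <- fx$wt$protein[fx$wt$protein$resno == phe_pos, ]
  ring_names <- c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")
  ring <- phe[match(ring_names, phe$elety), ]
  centroid <- colMeans(as.matrix(ring[, c("x", "y", "z")]))
  normal <- resmutscan:::ring_normal(as.matrix(ring[, c("x", "y", "z")]))
  r <- 1.39 / (2 * sin(pi / 6))
  e1 <- resmutscan:::vunit(as.numeric(ring[1, c("x", "y", "z")]) - centroid)
  e2 <- resmutscan:::vunit(resmutscan:::vcross(normal, e1))
  ang <- 2 * pi * (0:5) / 6
  benz <- t(vapply(ang, function(a)
    centroid + 3.8 * normal + r * (cos(a) * e1 + sin(a) * e2), numeric(3)))
  lig2 <- data.frame(type = "HETATM", eleno = 0L, elety = paste0("C", 1:6),
                     resid = "BNZ", chain = "A", resno = 1L,
                     x = benz[, 1], y = benz[, 2], z = benz[, 3],
                     o = 1, b = 0, element = "C", stringsAsFactors = FALSE)
  at <- rbind(fx$wt$protein, lig2)
  at$eleno <- seq_len(nrow(at))
  stack <- complex_model(at, "BNZ")
  fp2 <- ligand_interaction_fingerprint(stack, phe_pos)
  expect_true(fp2$pi_stacking$present)
  expect_equal(fp2$pi_stacking$distance, 3.8, tolerance = 0.05)
  expect_equal(fp2$pi_stacking$groups, "parallel")
  expect_true(fp2$hydrophobic$present)
  # halogen bond: ligand C-Cl axis pointing at a backbone oxygen at 3.2 A
  o_atom <- fx$wt$protein[fx$wt$protein$resno == 2 &
                            fx$wt$protein$elety == "O", ]
  O <- as.numeric(o_atom[1, c("x", "y", "z")])
  cl <- O + c(0, 3.2, 0)
  cc <- cl + c(0, 1.73, 0)   # C-Cl...O angle = 180
  lig3 <- data.frame(type = "HETATM", eleno = 0L, elety = c("CL1", "C1"),
                     resid = "HAL", chain = "A", resno = 1L,
                     x = c(cl[1], cc[1]), y = c(cl[2], cc[2]),
                     z = c(cl[3], cc[3]), o = 1, b = 0,
                     element = c("CL", "C"), stringsAsFactors = FALSE)
  at3 <- rbind(fx$wt$protein, lig3)
  at3$eleno <- seq_len(nrow(at3))
  hal <- complex_model(at3, "HAL")
  fp3 <- ligand_interaction_fingerprint(hal, 2)
  expect_true(fp3$halogen$present)
  expect_equal(fp3$halogen$distance, 3.2, tolerance = 1e-6)
  # angle rule: bent arrangement (~90 deg) is rejected
  lig4 <- lig3
  lig4[2, c("x", "y", "z")] <- cl + c(1.73, 0, 0)
  at4 <- rbind(fx$wt$protein, lig4)
  at4$eleno <- seq_len(nrow(at4))
  fp4 <- ligand_interaction_fingerprint(complex_model(at4, "HAL"), 2)
  expect_false(fp4$halogen$present)
  # ligand ring perception finds the toy aromatic ring
  expect_length(ligand_aromatic_rings(fx$wt), 1)
  # charged-group perception: carboxylate fixture near an arginine
  lig5 <- data.frame(type = "HETATM", eleno = 0L,
                     elety = c("C1", "O1", "O2"), resid = "CRX", chain = "A",
                     resno = 1L, x = c(0, 1.23, -0.6), y = c(0, 0, 1.1),
                     z = 0, o = 1, b = 0, element = c("C", "O", "O"),
                     stringsAsFactors = FALSE)
  arg <- resmutscan:::toy_residue_atoms("R", 1)
  nh1 <- as.numeric(arg[arg$elety == "NH1", c("x", "y", "z")])
  lig5[, c("x", "y", "z")] <- sweep(as.matrix(lig5[, c("x", "y", "z")]), 2,
                                    -(nh1 + c(0, 0, 3.5)))
  at5 <- rbind(arg, lig5)
  at5$eleno <- seq_len(nrow(at5))
  crx <- complex_model(at5, "CRX")
  grp <- ligand_charged_groups(crx)
  expect_true(any(vapply(grp, function(g) g$class == "carboxylate", logical(1))))
  sbf <- salt_bridge_features(crx, 1)
  expect_true(sbf$lig_present)
  expect_equal(sbf$lig_group, "carboxylate")
})

test_that("feature extraction is rigid-motion invariant and deterministic", {
  fx <- toy_fixture()
  m <- fx$mutants[[4]]
  mt <- build_mutant_model(fx$wt, m)$structure
  schema <- feature_schema("aa-v1")
  fv1 <- extract_features(fx$wt, mt, fx$site, m, schema, 50, "Ki",
                          n_points = 240)
  fv2 <- extract_features(fx$wt, mt, fx$site, m, schema, 50, "Ki",
                          n_points = 240)
  expect_identical(fv1$values, fv2$values)  # pure function of its inputs
  rot <- resmutscan:::rotation_matrix(c(0, 1, 1), 41)
  wt_r <- transform_complex(fx$wt, rot, c(7, -2, 3))
  mt_r <- transform_complex(mt, rot, c(7, -2, 3))
  fv3 <- extract_features(wt_r, mt_r, fx$site, m, schema, 50, "Ki",
                          n_points = 240)
  # geometric features agree under rigid motion (surface lattice points are
  # orientation-dependent, so allow a small integration tolerance there)
  sasa_keys <- grep("sasa|rsa|^ddg$", names(fv1$values), value = TRUE)
  # the planar toy chain puts CA neighbours exactly on the half-sphere
  # equator (CB axis is normal to the chain plane), so HSE counts are
  # tie-degenerate under rotation; exclude them here
  hse_keys <- grep("^hse_", names(fv1$values), value = TRUE)
  other <- setdiff(names(fv1$values), c(sasa_keys, hse_keys))
  expect_equal(fv1$values[other], fv3$values[other], tolerance = 1e-4)
  expect_equal(fv1$values[sasa_keys], fv3$values[sasa_keys], tolerance = 0.05)
})

test_that("assembled vectors conform to the schema registry", {
  fx <- toy_fixture()
  m <- fx$mutants[[4]]
  mt <- build_mutant_model(fx$wt, m)$structure
  aa <- extract_features(fx$wt, mt, fx$site, m, feature_schema("aa-v1"),
                         50, "Ki", n_points = 240)
  lig <- extract_features(fx$wt, mt, fx$site, m, feature_schema("lig-v1"),
                          50, "Ki", n_points = 240)
  expect_length(aa$values, length(feature_schema("aa-v1")$features))
  expect_length(lig$values, length(feature_schema("lig-v1")$features))
  expect_false(any(is.na(aa$values)))
  expect_false(any(is.na(lig$values)))
  # lig schema carries the fingerprint block and drops the aa-only families
  expect_true(any(grepl("^fp_", names(lig$values))))
  expect_false(any(grepl("^hse_|^disulfide_|^sb_pp_", names(lig$values))))
  expect_true(all(c("hse_up_wt", "disulfide_wt", "sb_pp_count_wt") %in%
                    names(aa$values)))
  expect_false(any(grepl("^fp_", names(aa$values))))
  # wild-type affinity encoding
  expect_equal(unname(aa$values["wt_affinity_log10nM"]), log10(50))
  expect_equal(unname(aa$values["measure_Ki"]), 1)
  # an identity pair zeroes every delta feature
  same <- extract_features(fx$wt, fx$wt, fx$site,
                           resmutscan:::new_aa_mutation(m$protein_position,
                                                        m$ref_aa, m$ref_aa,
                                                        list()),
                           feature_schema("aa-v1"), 50, "Ki", n_points = 240)
  expect_lt(max(abs(same$values[grep("absdiff|rmsd", names(same$values))])), 1e-4)
  # unknown parts surface as sentinel + provenance
  parts <- list(mutation = m)
  fv <- assemble_feature_vector(parts, feature_schema("aa-v1"), 10, "Kd")
  expect_equal(unname(fv$values["sasa_known"]), 0)
  expect_equal(unname(fv$provenance[["rsa_wt"]]), "unknown")
})
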