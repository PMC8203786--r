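test_that("PDB parsing reads atoms back and applies the stated record rules", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "B", 1, 3.5, 0, 0),
    "END"
  )
  m <- toy_model(lines, chain_map = c(A = "TnC", B = "TnI"))
  expect_equal(nrow(m$atoms), 2)
  expect_equal(sort(unique(m$atoms$chain)), c("A", "B"))
  expect_equal(unname(m$chain_to_entity["A"]), "TnC")

  # altloc: highest occupancy wins; ties broken by label order
  alt <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 1, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "GLY", "A", 1, 9, 0, 0, occ = 0.4, alt = "B"),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 5, 0, 0, occ = 0.5, alt = "B"),
    pdb_atom_line(4, "CA", "GLY", "A", 2, 7, 0, 0, occ = 0.5, alt = "A")
  )
  ma <- toy_model(alt)
  expect_equal(nrow(ma$atoms), 2)
  expect_equal(ma$atoms$x[ma$atoms$resno == 1], 1)   # occ 0.6 beats 0.4
  expect_equal(ma$atoms$x[ma$atoms$resno == 2], 7)   # tie: altloc A first

  # first model only; waters dropped; hetero calcium kept as ligand
  mm <- c(
    "MODEL        1",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "O", "HOH", "W", 1, 2, 2, 2, record = "HETATM", elesy = "O"),
    pdb_atom_line(3, "CA", "CA", "X", 1, 1, 1, 1, record = "HETATM", elesy = "CA"),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, "CA", "GLY", "A", 1, 50, 0, 0),
    "ENDMDL"
  )
  m2 <- toy_model(mm)
  expect_equal(nrow(m2$atoms), 2)          # water gone, model 2 gone
  expect_equal(m2$atoms$x[!m2$atoms$is_ligand], 0)
  expect_true(any(m2$atoms$is_ligand))
})

test_that("parse errors carry line numbers and empty models fail", {
  bad <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    "ATOM      2  CA  GLY A   2        abc   0.000   0.000  1.00  0.00           C"
  )
  expect_error(toy_model(bad), "line 2")
  expect_error(toy_model("REMARK nothing here"), "empty model")
})

test_that("planted geometry and the inclusive 4 A boundary are honoured", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "B", 1, 3.5, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "B", 2, 30, 0, 0)
  )
  ct <- interchain_contacts(toy_model(lines))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$min_distance, 3.5, tolerance = 1e-9)

  exact <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "B", 1, 4.0, 0, 0)
  )
  expect_equal(nrow(interchain_contacts(toy_model(exact))), 1)
  just_over <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "B", 1, 4.01, 0, 0)
  )
  expect_equal(nrow(interchain_contacts(toy_model(just_over))), 0)
})

test_that("hydrogens and ligands are excluded from the contact search", {
  lines <- c(
    pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "H", "GLY", "B", 1, 2, 0, 0, elesy = "H"),
    pdb_atom_line(3, "CA", "GLY", "B", 1, 10, 0, 0),
    pdb_atom_line(4, "CA", "CA", "X", 9, 1, 0, 0, record = "HETATM", elesy = "CA")
  )
  m <- toy_model(lines)
  expect_equal(nrow(interchain_contacts(m)), 0)
  # but the calcium ion is picked up by the calcium-binding annotation
  cb <- calcium_binding_residues(m)
  expect_equal(cb$pos, 1)
  expect_equal(cb$chain, "A")
})

test_that("single-chain model warns and yields an empty set", {
  lines <- c(pdb_atom_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdb_atom_line(2, "CA", "GLY", "A", 2, 3, 0, 0))
  expect_warning(ct <- interchain_contacts(toy_model(lines)), "fewer than two")
  expect_equal(nrow(ct), 0)
})

test_that("contact detection equals the all-pairs brute-force oracle", {
  for (seed in 1:10) {
    spec <- random_complex_spec(n_chains = 3, n_residues = 25,
                                n_contacts = 4, seed = seed)
    cx <- make_complex(n_chains = 3, n_residues = 25, planted = spec,
                       seed = seed)
    m <- toy_model(cx$pdb)
    got <- interchain_contacts(m)
    ora <- oracle_contacts(m$atoms)
    expect_equal(got$chain_a, ora$chain_a)
    expect_equal(got$pos_a, ora$pos_a)
    expect_equal(got$pos_b, ora$pos_b)
    expect_equal(got$min_distance, ora$min_distance, tolerance = 1e-9)
    # and the oracle set is the planted truth
    expect_equal(got[, c("chain_a", "pos_a", "chain_b", "pos_b")],
                 cx$truth[, c("chain_a", "pos_a", "chain_b", "pos_b")],
                 ignore_attr = TRUE)
  }
})

test_that("contact sets are monotone in the cutoff", {
  cx <- make_complex(planted = random_complex_spec(seed = 11), seed = 11)
  m <- toy_model(cx$pdb)
  key <- function(ct) paste(ct$chain_a, ct$pos_a, ct$chain_b, ct$pos_b)
  prev <- character(0)
  for (cutoff in c(2, 3, 4, 6, 10)) {
    cur <- key(interchain_contacts(m, cutoff = cutoff))
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("residue maps pair ungapped columns and round-trip", {
  aln <- c(src = "AC-DE", tgt = "ACQDE")
  m <- build_residue_map(aln, "src", "tgt")
  expect_equal(m$source_pos, 1:4)
  expect_equal(m$target_pos, c(1, 2, 4, 5))

  ident <- c(a = "MKVL", b = "MKVL")
  mi <- build_residue_map(ident, "a", "b")
  expect_equal(mi$source_pos, mi$target_pos)

  # random gapped pairs vs the column-walking oracle; composition = identity
  set.seed(42)
  for (i in 1:20) {
    n <- 30
    s <- paste(sample(c(strsplit("ACDEFG", "")[[1]], "-"), n, TRUE), collapse = "")
    t <- paste(sample(c(strsplit("ACDEFG", "")[[1]], "-"), n, TRUE), collapse = "")
    aln <- c(s = s, t = t)
    m <- build_residue_map(aln, "s", "t")
    ora <- oracle_residue_map(s, t)
    if (is.null(ora)) {
      expect_equal(nrow(m), 0)
    } else {
      expect_equal(as.data.frame(m), ora, ignore_attr = TRUE)
    }
    back <- build_residue_map(aln, "t", "s")
    expect_equal(m$source_pos,
                 back$target_pos[match(m$target_pos, back$source_pos)])
  }
  expect_error(build_residue_map(aln, "nope", "t"), "not found")
  expect_error(build_residue_map(c(a = "AA", a = "AA", b = "AA"), "a", "b"),
               "duplicate")
})

test_that("state classification is the three-way set algebra", {
  # entity_a sorts before entity_b so canonical ordering keeps orientation
  mk <- function(pairs) {
    tibble::tibble(entity_a = "TnC", pos_a = pairs[, 1], aa_a = "X",
                   entity_b = "TnI", pos_b = pairs[, 2], aa_b = "X",
                   min_distance = 3)
  }
  bound <- mk(cbind(c(1, 3), c(10, 30)))
  free <- mk(cbind(c(3, 5), c(30, 50)))
  cl <- classify_contact_states(bound, free)
  expect_equal(nrow(cl), 3)
  expect_equal(cl$state_class[cl$pos_a == 1], "bound_only")
  expect_equal(cl$state_class[cl$pos_a == 3], "common")
  expect_equal(cl$state_class[cl$pos_a == 5], "free_only")

  # free empty -> everything bound_only
  cl2 <- classify_contact_states(bound, mk(cbind(integer(0), integer(0))))
  expect_true(all(cl2$state_class == "bound_only"))

  # random sets vs membership oracle
  set.seed(7)
  for (i in 1:5) {
    pb <- unique(cbind(sample(50, 40, TRUE), sample(50, 40, TRUE)))
    pf <- unique(cbind(sample(50, 40, TRUE), sample(50, 40, TRUE)))
    cl <- classify_contact_states(mk(pb), mk(pf))
    kb <- paste(pb[, 1], pb[, 2]); kf <- paste(pf[, 1], pf[, 2])
    expect_equal(nrow(cl), length(union(kb, kf)))
    for (j in seq_len(nrow(cl))) {
      k <- paste(cl$pos_a[j], cl$pos_b[j])
      expected <- if (k %in% kb && k %in% kf) "common"
                  else if (k %in% kb) "bound_only" else "free_only"
      expect_equal(cl$state_class[j], expected)
    }
  }
})

test_that("renumbering drops unmapped endpoints with a message", {
  ct <- tibble::tibble(entity_a = "TnT", chain_a = "A", pos_a = c(5L, 6L),
                       aa_a = "X", entity_b = "TnI", chain_b = "B",
                       pos_b = c(1L, 2L), aa_b = "X", min_distance = 3)
  maps <- list(TnT = tibble::tibble(source_pos = 5L, target_pos = 105L))
  expect_message(out <- renumber_contacts(ct, maps), "dropped")
  expect_equal(out$pos_a, 105L)
  expect_equal(out$pos_b, 1L)   # TnI has no map: left unchanged
})
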