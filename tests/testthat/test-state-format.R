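test_that("serialization emits one line per grid location, row-major", {
  s <- random_state(1, n_rows = 5, n_cols = 7)
  for (mode in c("all", "cells_only", "molecules_only")) {
    txt <- rawToChar(canonical_serialize(s, mode))
    lines <- strsplit(txt, "\n")[[1]]
    expect_length(lines, 35L)
    expect_identical(sub("\t.*", "", lines[1]), "0,0")
    expect_identical(sub("\t.*", "", lines[8]), "1,0")
    expect_identical(sub("\t.*", "", lines[35]), "4,6")
  }
  s20 <- initialize_state(sim_config(seed = 3L))
  expect_length(strsplit(rawToChar(write_state_file(s20)), "\n")[[1]], 400L)
})

test_that("read after write is the identity on the state data model", {
  for (seed in 1:200) {
    s <- random_state(seed)
    b <- canonical_serialize(s)
    s2 <- read_state_file(b, t = s$t)
    expect_same_state(s, s2)
    expect_identical(canonical_serialize(s2), b)  # write o read o write
  }
})

test_that("canonical serialization is invariant to container ordering", {
  s <- random_state(11)
  perm <- s
  if (nrow(perm$cells) > 1)
    perm$cells <- perm$cells[rev(seq_len(nrow(perm$cells))), ]
  if (nrow(perm$receptors) > 1)
    perm$receptors <- perm$receptors[sample(nrow(perm$receptors)), ]
  if (nrow(perm$molecules) > 1)
    perm$molecules <- perm$molecules[rev(seq_len(nrow(perm$molecules))), ]
  expect_identical(canonical_serialize(perm), canonical_serialize(s))
  b1 <- canonical_serialize(s)
  expect_identical(b1, canonical_serialize(s))  # pure function
})

test_that("feature-restricted modes suppress the right segments", {
  s <- random_state(21, max_cells = 8, max_mols = 15)
  txt_c <- rawToChar(canonical_serialize(s, "cells_only"))
  expect_false(grepl("MOLECULES:", txt_c, fixed = TRUE))
  txt_m <- rawToChar(canonical_serialize(s, "molecules_only"))
  expect_false(grepl("CELLS:", txt_m, fixed = TRUE))

  ## cells_only view of a molecules-only state: bare location ids
  mol_only <- system_state(t = 0, n_rows = 3, n_cols = 3,
                           molecules = data.frame(row = 1, col = 2,
                                                  name = "IL-10", conc = 1.5))
  lines <- strsplit(rawToChar(canonical_serialize(mol_only, "cells_only")),
                    "\n")[[1]]
  expect_identical(lines, c("0,0", "0,1", "0,2", "1,0", "1,1", "1,2",
                            "2,0", "2,1", "2,2"))
})

test_that("an empty-grid file reads back as an empty state", {
  empty <- system_state(t = 0, n_rows = 20, n_cols = 20)
  b <- canonical_serialize(empty)
  expect_length(strsplit(rawToChar(b), "\n")[[1]], 400L)
  s <- read_state_file(b)
  expect_identical(nrow(s$cells), 0L)
  expect_identical(nrow(s$molecules), 0L)
})

test_that("a single-cell state round-trips exactly", {
  s <- system_state(t = 0, n_rows = 20, n_cols = 20,
                    cells = data.frame(index = 1L, name = "Treg",
                                       lifespan = 10L, behavior = "Resting",
                                       row = 0L, col = 0L),
                    receptors = data.frame(cell_index = 1L, name = "TLR2",
                                           level = 5))
  s2 <- read_state_file(canonical_serialize(s))
  expect_identical(s2$cells$name, "Treg")
  expect_identical(s2$receptors$level, 5)
  expect_same_state(s, s2)
})

test_that("malformed input is rejected with the offending line", {
  s <- random_state(31)
  txt <- rawToChar(canonical_serialize(s))
  bad <- sub("IL-10\t", "IL-11\t", txt, fixed = TRUE)
  if (!identical(bad, txt)) {
    err <- tryCatch(read_state_file(charToRaw(bad)), error = conditionMessage)
    expect_match(err, "line \\d+")
  }
  expect_error(read_state_file(charToRaw("0,0\tMOLECULES:\tIL-10\t-3.0\n")),
               "negative concentration")
  expect_error(read_state_file(charToRaw("0,0\tCELLS:\t1\tNotACell\t5\tResting\n")),
               "unknown cell name")
  expect_error(read_state_file(charToRaw("xyz\n")), "location")
  expect_error(canonical_serialize(random_state(1), "everything"),
               "feature_mode")
})

test_that("states with invariant violations are rejected", {
  good <- random_state(41, max_cells = 5)
  dup <- good
  if (nrow(dup$cells) >= 2) {
    dup$cells$index[2] <- dup$cells$index[1]
    expect_error(canonical_serialize(dup), "unique")
  }
  neg <- system_state(t = 0, n_rows = 2, n_cols = 2)
  expect_error(system_state(t = 0, n_rows = 2, n_cols = 2,
                            molecules = data.frame(row = 0, col = 0,
                                                   name = "IL-10", conc = -1)),
               "non-negative")
})

test_that("write_state_file writes files readable by read_state_file", {
  s <- random_state(51)
  p <- tempfile(fileext = ".txt")
  write_state_file(s, path = p)
  expect_same_state(s, read_state_file(p, t = s$t))
  unlink(p)
})

test_that("run_result enforces a gapless time course", {
  states <- lapply(0:3, function(t) system_state(t = t, n_rows = 2, n_cols = 2))
  expect_s3_class(run_result(0, "wt", states), "run_result")
  expect_error(run_result(0, "wt", states[c(1, 3)]), "ordered")
})
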