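# Shared fixtures, built once per test run.

fixture_library_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "structannot-fixture-lib")
      if (!dir.exists(dir)) write_fixture_library(dir, seed = 1)
    }
    dir
  }
})

fixture_index <- function() build_template_index(fixture_library_dir())

fixture_sequence <- function(entry_id, chain_id = "A") {
  idx <- fixture_index()
  idx$sequence[idx$entry_id == entry_id & idx$chain_id == chain_id]
}

# hand-built mini PDB text for parser edge cases
pdb_line <- function(record = "ATOM", serial, name, altloc = " ",
                     resname, chain, resnum, icode = " ", x, y, z,
                     occ = 1, b = 20, element) {
  nm4 <- if (nchar(name) < 4) formatC(paste0(" ", name), width = 4,
                                      flag = "-") else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm4, altloc, resname, chain, resnum, icode,
          x, y, z, occ, b, element)
}

write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# a residue buried inside a cubic cage of occluding pseudo-atoms
caged_residue_model <- function(spacing = 2.5) {
  helix <- generate_fixture("helix", n = 5, seed = 9)$model
  lines <- character(0)
  serial <- 1L
  a <- helix$atoms
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, pdb_line("ATOM", serial, a$name[i],
                               resname = a$resname[i], chain = "A",
                               resnum = a$resnum[i], x = a$x[i], y = a$y[i],
                               z = a$z[i], element = a$element[i]))
    serial <- serial + 1L
  }
  # dense cage of carbon "ligand" atoms surrounding residue 3
  ca3 <- a[a$resnum == 3 & a$name == "CA", c("x", "y", "z")]
  grid <- expand.grid(dx = -2:2, dy = -2:2, dz = -2:2)
  grid <- grid[rowSums(abs(grid) == 2) > 0, ]   # hollow shell
  for (i in seq_len(nrow(grid))) {
    lines <- c(lines, pdb_line("HETATM", serial, "C1", resname = "CG" ,
                               chain = "X", resnum = i,
                               x = ca3$x + spacing * grid$dx[i],
                               y = ca3$y + spacing * grid$dy[i],
                               z = ca3$z + spacing * grid$dz[i],
                               element = "C"))
    serial <- serial + 1L
  }
  parse_structure(write_mini_pdb(lines), "CAGE")
}
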