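# Shared fixtures: small synthetic configurations and toy tables built
# in code at test time.

tiny_config <- function(seed = 42, ...) {
  sim_config(n_subjects = 25, n_species = 40, seed = seed, ...)
}

fast_merf <- function(n_trees = 100, max_iter = 10, ...) {
  merf_control(n_trees = n_trees, max_iter = max_iter, ...)
}

# two-sample, three-species table with columns summing to 100
toy_species <- function() {
  vals <- matrix(c(50, 30, 20,
                   10, 70, 20), nrow = 3,
                 dimnames = list(
                   c("k__Bacteria|g__A|s__A_x",
                     "k__Bacteria|g__A|s__A_y",
                     "k__Bacteria|g__B|s__B_z"),
                   c("S1", "S2")))
  species_table(vals)
}

# one pathway split over two genera (three strata; genus A split in two
# species rows), plus UNMAPPED
toy_pathways <- function() {
  keys <- c("PWY-X: toy pathway",
            "PWY-X: toy pathway|g__A.s__A_x",
            "PWY-X: toy pathway|g__A.s__A_y",
            "PWY-X: toy pathway|g__B.s__B_z",
            "UNMAPPED")
  vals <- rbind(c(10, 20, 5, 0),
                c(3, 8, 1, 0),
                c(3, 4, 1, 0),
                c(4, 8, 3, 0),
                c(100, 100, 100, 100))
  colnames(vals) <- paste0("S", 1:4)
  pathway_table(vals, row_keys = keys)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
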