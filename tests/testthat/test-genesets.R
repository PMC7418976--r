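# Gene sets: file loading, nested random families, ortholog restriction,
# variance screen.

write_lines_tmp <- function(lines) {
  f <- withr::local_tempfile(fileext = ".txt",
                             .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("gene-set files load in order, de-duplicated, with errors on empty", {
  f <- write_lines_tmp(c("G3", "G1", "G2", "", "G1"))
  expect_warning(gs <- load_gene_set(f, "demo"), "duplicate")
  expect_equal(gs$gene_ids, c("G3", "G1", "G2"))  # order preserved
  expect_equal(length(gs), 3L)
  f76 <- write_lines_tmp(sprintf("GENE%02d", 1:76))
  expect_silent(gs76 <- load_gene_set(f76))
  expect_equal(length(gs76), 76L)
  fe <- write_lines_tmp(character(0))
  expect_error(load_gene_set(fe), "empty")
  expect_error(load_gene_set(file.path(tempdir(), "no-such-file.txt")),
               "no such file")
})

test_that("nested random sets have the documented sizes and strict nesting", {
  universe <- sprintf("g%03d", 1:200)
  fam <- generate_nested_random_sets(universe, core_size = 20L,
                                     increment = 15L, n_levels = 5L,
                                     seed = 4L)
  expect_equal(vapply(fam, length, 0L), c(20L, 35L, 50L, 65L, 80L))
  for (k in 2:5) {
    expect_true(all(fam[[k - 1L]]$gene_ids %in% fam[[k]]$gene_ids))
    expect_identical(fam[[k]]$parent, fam[[k - 1L]])
    expect_false(anyDuplicated(fam[[k]]$gene_ids) > 0L)
  }
  # determinism and seed sensitivity
  fam2 <- generate_nested_random_sets(universe, seed = 4L)
  expect_identical(lapply(fam, `[[`, "gene_ids"),
                   lapply(fam2, `[[`, "gene_ids"))
  fam3 <- generate_nested_random_sets(universe, seed = 5L)
  expect_false(identical(fam[[1L]]$gene_ids, fam3[[1L]]$gene_ids))
  # single level: just the core
  one <- generate_nested_random_sets(universe, core_size = 7L, n_levels = 1L,
                                     seed = 1L)
  expect_length(one, 1L)
  expect_equal(length(one[[1L]]), 7L)
  expect_error(generate_nested_random_sets(universe[1:40]), "too small")
})

test_that("ortholog restriction keeps order and handles edge cases", {
  universe <- sprintf("rat%02d", 1:10)
  map <- ortholog_map(sprintf("rat%02d", c(2, 5, 7, 99)),
                      sprintf("hum%02d", c(2, 5, 7, 99)))
  expect_equal(restrict_to_orthologs(universe, map),
               c("rat02", "rat05", "rat07"))   # map-only ids ignored
  empty_map <- ortholog_map(character(0), character(0))
  expect_warning(out <- restrict_to_orthologs(universe, empty_map),
                 "no genes")
  expect_length(out, 0L)
  expect_error(ortholog_map(c("a", "a"), c("x", "y")), "duplicate source")
  gs <- gene_set("core", c("rat05", "rat02"))
  mapped <- map_gene_set(gs, map)
  expect_equal(mapped$gene_ids, c("hum05", "hum02"))
  expect_error(map_gene_set(gene_set("bad", "rat01"), map), "missing")
})

test_that("ortholog maps round-trip through TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  map <- ortholog_map(c("r1", "r2"), c("h1", "h2"))
  utils::write.table(map, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_ortholog_map(f)
  expect_equal(back$source_id, map$source_id)
  expect_equal(back$target_id, map$target_id)
})

# hand-built dataset with exactly known per-gene variances
flat_dataset <- function(gene_values) {
  design <- domain_design("d", c(2, 8), 2L, c("control", "high"))
  genes <- names(gene_values)
  md <- expand.grid(replicate = 1:2, time_h = c(2, 8),
                    dose = c("control", "high"), compound = "c1",
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  md$sample_id <- sprintf("s%d", seq_len(nrow(md)))
  expr <- do.call(rbind, gene_values)
  rownames(expr) <- genes
  colnames(expr) <- md$sample_id
  domain_dataset(design, genes, expr, md)
}

test_that("variance screen is inclusive at the boundary and scale-covariant", {
  p <- c(1, 2, 3, 4, 5, 6, 7, 8)                   # var = 6
  shrink <- function(f) mean(p) + (p - mean(p)) * sqrt(f)
  ds <- flat_dataset(list(ref = p,
                          at_boundary = shrink(0.97),
                          below = shrink(0.9599),
                          const = rep(5, 8)))
  ref <- gene_set("ref", "ref")
  expect_true(screen_variance(gene_set("s", "at_boundary"), ds, ref))
  expect_false(screen_variance(gene_set("s", "below"), ds, ref))
  expect_true(screen_variance(ref, ds, ref))       # candidate = reference
  expect_false(screen_variance(gene_set("s", "const"), ds, ref))
  # scale covariance: multiplying all expression by c leaves decisions alone
  ds10 <- flat_dataset(list(ref = 10 * p,
                            at_boundary = 10 * shrink(0.97),
                            below = 10 * shrink(0.9599)))
  expect_true(screen_variance(gene_set("s", "at_boundary"), ds10, ref))
  expect_false(screen_variance(gene_set("s", "below"), ds10, ref))
  expect_error(screen_variance(gene_set("s", "nope"), ds, ref), "missing")
})

test_that("screened nested generation redraws until the family passes", {
  # half the genes are constant: families drawn purely from constants fail
  coh <- tiny_cohort(n_compounds = 3L, n_genes = 40L, noise = 0,
                     frac_constant = 0.5)
  responsive <- setdiff(seq_len(40L), coh$truth$const_src)
  ref <- gene_set("ref", coh$source$gene_ids[responsive])
  fam <- generate_nested_random_sets(coh$source$gene_ids, core_size = 5L,
                                     increment = 5L, n_levels = 3L, seed = 2L,
                                     dataset = coh$source, reference = ref,
                                     tolerance = 0.5)
  for (s in fam)
    expect_true(screen_variance(s, coh$source, ref, tolerance = 0.5))
  # an impossible screen exhausts its retries
  expect_error(
    generate_nested_random_sets(coh$source$gene_ids[coh$truth$const_src],
                                core_size = 5L, increment = 5L, n_levels = 2L,
                                seed = 2L, dataset = coh$source,
                                reference = ref, max_retries = 3L),
    "variance screen")
})
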