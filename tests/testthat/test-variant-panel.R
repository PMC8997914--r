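write_variant_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

test_that("panel loading normalizes, de-duplicates and rejects empties", {
  f <- tempfile()
  writeLines(c("# apoptosis panel", "TP53", "ATM ", "PIK3CB", "PIK3R1",
               "NTRK1", "CSF2RB"), f)
  p <- load_panel(f)
  expect_s3_class(p, "gene_panel")
  expect_equal(sort(p$genes),
               c("ATM", "CSF2RB", "NTRK1", "PIK3CB", "PIK3R1", "TP53"))
  writeLines(c("TP53", "tp53"), f)
  expect_equal(load_panel(f)$genes, "TP53")
  writeLines(c("# only a comment", ""), f)
  expect_error(load_panel(f), "empty-panel")
})

test_that("variant TSV parses to one record per row with mapped classes", {
  path <- write_variant_tsv(ref_variants())
  v <- parse_variants(path)
  expect_equal(nrow(v), 11L)
  expect_equal(sum(v$specimen_id == "AFN111b"), 2L)
  expect_setequal(unique(v$consequence),
                  c("missense", "nonsense", "frameshift"))
  expect_true(all(v$lof_class == "unknown"))
})

test_that("annotation vocabulary maps onto the closed consequence set", {
  df <- ref_variants()[1:5, ]
  df$consequence <- c("stop_gained", "missense_variant",
                      "frameshift_variant", "splice_donor_variant",
                      "synonymous_variant")
  v <- parse_variants(write_variant_tsv(df))
  expect_equal(v$consequence,
               c("nonsense", "missense", "frameshift", "splice", "other"))
})

test_that("variant TSV format errors and empty files are handled", {
  f <- tempfile(fileext = ".tsv")
  writeLines("specimen_id\tgene\nS1\tTP53", f)
  expect_error(parse_variants(f), "missing column")
  writeLines(paste("specimen_id", "gene", "genomic_change",
                   "protein_change", "consequence", sep = "\t"), f)
  expect_equal(nrow(parse_variants(f)), 0L)
})

test_that("annotated VCF records are ingested through the same surface", {
  skip_if_not_installed("vcfR")
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ANN,Number=.,Type=String,Description=\"Functional annotations\">",
    "##contig=<ID=17>",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    paste0("17\t7675234\t.\tG\tC\t.\tPASS\t",
           "ANN=C|stop_gained|HIGH|TP53|gene1|transcript|tx1|protein|1/11|",
           "c.378C>G|p.Y126*"),
    paste0("17\t7674954\t.\tG\tA\t.\tPASS\t",
           "ANN=A|missense_variant|MODERATE|TP53|gene1|transcript|tx1|",
           "protein|1/11|c.577C>T|p.H193Y")
  ), f)
  v <- parse_variants(f, format = "vcf", specimen_id = "AF50b")
  expect_equal(nrow(v), 2L)
  expect_equal(v$consequence, c("nonsense", "missense"))
  expect_equal(v$gene, c("TP53", "TP53"))
  expect_equal(v$protein_change, c("p.Y126*", "p.H193Y"))
  expect_match(v$genomic_change[1], "g.chr17:7675234G>C", fixed = TRUE)
})

test_that("mutation matrix covers the whole cohort with explicit zeros", {
  rc <- ref_cohort()
  m <- build_mutation_matrix(rc$variants, rc$panel, rc$specimens)
  expect_equal(nrow(m), 37L)
  expect_equal(sum(mutation_status(m)), 10L)
  expect_equal(sum(!mutation_status(m)), 27L)
  expect_equal(unname(m["AFN111b", c("ATM", "NTRK1")]), c(1L, 1L))
  expect_equal(unname(m["AF98b", "TP53"]), 1L)
  expect_true(all(m %in% 0:1))
})

test_that("variants outside the panel or cohort are rejected or ignored", {
  rc <- ref_cohort()
  off_panel <- ref_variants()
  off_panel$gene <- "KRAS"
  m <- build_mutation_matrix(off_panel, rc$panel, rc$specimens)
  expect_equal(ncol(m), 0L)
  expect_false(any(mutation_status(m)))
  stranger <- ref_variants()
  stranger$specimen_id[1] <- "NOBODY"
  expect_error(build_mutation_matrix(stranger, rc$panel, rc$specimens),
               "unknown-specimen")
})

test_that("non-qualifying consequences and cosmic filtering are applied", {
  rc <- ref_cohort()
  v <- rc$variants
  v$consequence[v$specimen_id == "AF85b"] <- "other"
  m <- build_mutation_matrix(v, rc$panel, rc$specimens)
  expect_false(mutation_status(m)[["AF85b"]])
  # cosmic filter drops the two variants without IDs
  m2 <- build_mutation_matrix(rc$variants, rc$panel, rc$specimens,
                              require_cosmic = TRUE)
  expect_false(mutation_status(m2)[["AF85b"]])   # CSF2RB has no ID
  expect_true(mutation_status(m2)[["AFN111b"]])  # ATM still qualifies
})

test_that("binarization is idempotent and panel growth is monotone", {
  rc <- ref_cohort()
  dup <- rbind(rc$variants, rc$variants[1, ])
  expect_equal(build_mutation_matrix(dup, rc$panel, rc$specimens),
               build_mutation_matrix(rc$variants, rc$panel, rc$specimens))
  small <- load_panel(c("TP53"))
  big <- load_panel(c("TP53", "ATM", "PIK3CB", "PIK3R1", "NTRK1",
                      "CSF2RB", "BAX"))
  s_small <- mutation_status(
    build_mutation_matrix(rc$variants, small, rc$specimens))
  s_big <- mutation_status(
    build_mutation_matrix(rc$variants, big, rc$specimens))
  expect_true(all(s_big[s_small]))  # enlarging never flips Mut+ to Mut-
})

test_that("lof overrides update matching records and warn on misses", {
  rc <- ref_cohort()
  v <- apply_lof_overrides(rc$variants, rc$lof_overrides)
  expect_equal(v$lof_class[v$specimen_id == "AF98b"], "partial")
  expect_true(all(v$lof_class[v$specimen_id != "AF98b"] == "unknown"))
  expect_identical(apply_lof_overrides(rc$variants, NULL), rc$variants)
  miss <- data.frame(specimen_id = "NOBODY", gene = "TP53",
                     protein_change = "p.X1Y", lof_class = "partial")
  expect_warning(out <- apply_lof_overrides(rc$variants, miss),
                 "matched no variant")
  expect_identical(out, rc$variants)
})

test_that("mutation matrix TSV round-trips exactly", {
  rc <- ref_cohort()
  m <- build_mutation_matrix(rc$variants, rc$panel, rc$specimens)
  f <- tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  back <- read_matrix_tsv(f)
  expect_equal(unclass(back)[, colnames(m)], unclass(m)[, colnames(m)])
})
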