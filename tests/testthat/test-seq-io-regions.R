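test_that("FASTA records parse with delimited headers, in file order", {
  path <- write_temp_fasta(c(
    ">MK522197|D. longicorna|Formosae", "ACGTACGTAC",
    ">x2", "GGGCCC"))
  recs <- read_its_fasta(path)
  expect_length(recs, 2L)
  expect_equal(recs[[1]]$id, "MK522197")
  expect_equal(recs[[1]]$species, "D. longicorna")
  expect_equal(recs[[1]]$section, "Formosae")
  expect_equal(recs[[2]]$id, "x2")
  expect_equal(recs[[2]]$section, "unknown")
})

test_that("FASTA validation rejects bad input with informative errors", {
  expect_error(read_its_fasta(write_temp_fasta(c(">a", "ACGT", ">a", "ACGT"))),
               "duplicate id.*a")
  expect_error(read_its_fasta(write_temp_fasta(c(">x", "ACGU"))),
               "non-IUPAC.*position 4")
  ## but U is accepted in RNA mode
  expect_length(read_its_fasta(write_temp_fasta(c(">x", "ACGU")), rna = TRUE), 1L)
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_its_fasta(empty), "empty")
})

test_that("partition recovers the construction of a synthetic amplicon", {
  ref <- study_ref58s()
  rec <- its_record("amp1", make_amplicon(ref, 228L, 247L))
  rec <- partition_regions(rec, ref)
  st <- region_stats(rec)
  expect_equal(unname(st$lengths[c("ITS1", "5.8S", "ITS2")]), c(228, 163, 247))
  expect_equal(unname(st$lengths["ITS"]), 228 + 163 + 247)
  ## concatenating the three regions reproduces the amplicon
  rp <- rec$regions
  expect_identical(rec$seq[(rp$its1[1] + 1):rp$its2[2]], rec$seq)
  ## idempotence: re-partitioning returns identical intervals
  rec2 <- partition_regions(its_record("amp1", rec$seq), ref)
  expect_identical(rec2$regions, rec$regions)
})

test_that("partition tolerates 5.8S point mutations but enforces identity floor", {
  ref <- study_ref58s()
  mut <- ref
  mut[c(10, 50, 90, 130)] <- c("A", "A", "A", "A")  # may or may not change
  rec <- partition_regions(its_record("m", make_amplicon(mut)), ref)
  expect_equal(rec$regions$r58s[2] - rec$regions$r58s[1], 163L)
  scrambled <- fixed_bases(163L, salt = 99L)
  expect_error(
    partition_regions(its_record("s", make_amplicon(scrambled)), ref),
    "5.8S anchor not found")
})

test_that("primer tails are trimmed before partitioning", {
  ref <- study_ref58s()
  core <- make_amplicon(ref, 60L, 70L)
  fwd <- fixed_bases(22L, salt = 31L)
  rev_site <- fixed_bases(22L, salt = 32L)
  tailed <- c(fixed_bases(20L, salt = 33L), fwd, core, rev_site,
              fixed_bases(20L, salt = 34L))
  plain <- partition_regions(its_record("p", core), ref)
  rec <- partition_regions(
    its_record("t", tailed), ref,
    primers = list(fwd = fwd, rev = paste(rev(chartr("ACGT", "TGCA", rev_site)),
                                          collapse = "")))
  expect_identical(rec$seq, core)
  expect_identical(rec$regions, plain$regions)
})

test_that("degenerate partitions are rejected", {
  ref <- study_ref58s()
  expect_error(partition_regions(its_record("r", ref), ref), "length 0")
  expect_error(partition_regions(its_record("r", c(ref, fixed_bases(50))),
                                 ref), "ITS1 has length 0")
})

test_that("GC content follows the unambiguous-base convention", {
  rec <- its_record("x", c(rep("A", 150), strsplit("GGCC", "")[[1]], rep("A", 150)))
  rec$regions <- region_partition(c(0L, 150L), c(150L, 154L), c(154L, 304L))
  st <- region_stats(rec)
  expect_equal(unname(st$gc[["5.8S"]]), 100.0)
  expect_equal(unname(st$gc[["ITS1"]]), 0.0)
  rec$seq[151:154] <- c("A", "C", "G", "T")
  expect_equal(unname(region_stats(rec)$gc[["5.8S"]]), 50.0)
  ## ambiguity codes drop out of numerator and denominator
  rec$seq[151:154] <- c("G", "C", "N", "R")
  expect_equal(unname(region_stats(rec)$gc[["5.8S"]]), 100.0)
  ## all-ambiguous region errors
  rec$seq[151:154] <- c("N", "N", "R", "Y")
  expect_error(region_stats(rec), "only ambiguity")
})

test_that("GC is invariant under reverse-complement of a region", {
  for (salt in 1:5) {
    x <- fixed_bases(97L, salt)
    rc <- rev(chartr("ACGT", "TGCA", paste(x, collapse = "")))
    rc <- strsplit(chartr("ACGT", "TGCA", paste(rev(x), collapse = "")), "")[[1]]
    gc <- function(v) 100 * sum(v %in% c("G", "C")) / length(v)
    expect_equal(gc(x), gc(rc))
  }
})

test_that("section summaries average unrounded GC and range over lengths", {
  ref <- study_ref58s()
  mk <- function(id, salt, sec) {
    r <- its_record(id, make_amplicon(ref, 200L + salt, 240L, salt),
                    section = sec)
    partition_regions(r, ref)
  }
  recs <- list(mk("a", 1L, "Formosae"), mk("b", 5L, "Formosae"),
               mk("c", 9L, "Chrysotoxae"))
  sm <- summarize_sections(recs)
  frow <- sm[sm$section == "Formosae" & sm$region == "ITS1", ]
  expect_equal(frow$n, 2L)
  expect_equal(frow$len_min, 201)
  expect_equal(frow$len_max, 205)
  g1 <- dendrobarcode:::exact_gc(recs[[1]], "ITS1")
  g2 <- dendrobarcode:::exact_gc(recs[[2]], "ITS1")
  expect_equal(frow$gc_mean, round_half_up(mean(c(g1, g2)), 1))
  ## single-record group: min = max, mean = that record's GC
  crow <- sm[sm$section == "Chrysotoxae" & sm$region == "ITS", ]
  expect_equal(crow$len_min, crow$len_max)
})

test_that("printed per-species values are internally consistent with the printed section means", {
  t2 <- dendrobium_table2()
  f <- t2[t2$section == "Formosae", ]
  c6 <- t2[t2$section == "Chrysotoxae", ]
  expect_equal(round_half_up(mean(f$gc_its), 1), 53.6)
  expect_equal(round_half_up(mean(f$gc_its1), 1), 52.7)
  expect_equal(round_half_up(mean(f$gc_58s), 1), 57.8)
  expect_equal(round_half_up(mean(f$gc_its2), 1), 51.8)
  expect_equal(round_half_up(mean(c6$gc_its), 1), 52.5)
  expect_equal(range(f$len_its), c(630, 646))
  expect_equal(max(c6$len_its), 651)
})

test_that("GenBank flat files parse, using region features when annotated", {
  gb <- c(
    "LOCUS       TEST0001                 30 bp    DNA     linear   PLN",
    "DEFINITION  toy record.",
    "ACCESSION   TEST0001",
    "  ORGANISM  Dendrobium toyense",
    "FEATURES             Location/Qualifiers",
    "     misc_RNA        1..10",
    "                     /note=\"internal transcribed spacer 1\"",
    "     rRNA            11..20",
    "                     /product=\"5.8S ribosomal RNA\"",
    "     misc_RNA        21..30",
    "                     /note=\"internal transcribed spacer 2\"",
    "ORIGIN",
    "        1 acgtacgtac ggggccccgg ttttaaaatt",
    "//")
  path <- withr::local_tempfile(fileext = ".gb")
  writeLines(gb, path)
  recs <- read_genbank(path)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "TEST0001")
  expect_equal(length(recs[[1]]$seq), 30L)
  expect_false(is.null(recs[[1]]$regions))
  expect_equal(recs[[1]]$regions$r58s, c(10L, 20L))
  st <- region_stats(recs[[1]])
  expect_equal(unname(st$gc[["5.8S"]]), 100.0)
})
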