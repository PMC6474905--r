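test_that("dot-bracket structures parse, validate and reject malformed input", {
  st <- secondary_structure("GGGAAAUCCC", "(((....)))")
  expect_equal(sum(st$pairs > 0) / 2, 3)
  expect_error(secondary_structure("GGGAA", "((..)"), "unbalanced '\\('")
  expect_error(secondary_structure("GGGAAC", "((.))("), "unbalanced")
  expect_error(secondary_structure("GGAAACC", "[[...]]"), "pseudoknot")
  expect_error(secondary_structure("GGGAAAUCCC", "(((....))"), "lengths differ")
  ## complementarity validation is opt-in
  expect_silent(secondary_structure("GGGAAAGGG", "(((...)))"))
  expect_error(secondary_structure("GGGAAAGGG", "(((...)))", validate = TRUE),
               "non-complementary")
  ## DNA input is transcribed
  expect_equal(secondary_structure("GGTAATACC", "((.....))")$seq[3], "U")
})

test_that("vienna and CT files convert losslessly", {
  st <- toy_four_helix(spacers = c(2L, 1L, 3L, 0L))
  vf <- withr::local_tempfile(fileext = ".fold")
  write_vienna(st, vf, id = "toy")
  back <- parse_structure(vf)
  expect_identical(back$db, st$db)
  expect_identical(back$seq, st$seq)
  expect_equal(attr(back, "id"), "toy")
  ## equivalent CT file gives the identical dot-bracket
  ct <- withr::local_tempfile(fileext = ".ct")
  writeLines(c(sprintf("%d toy", length(st$seq)),
               vapply(seq_along(st$seq), function(i) {
                 sprintf("%d %s %d %d %d %d", i, st$seq[i], i - 1L, i + 1L,
                         st$pairs[i], i)
               }, character(1))), ct)
  expect_identical(parse_structure(ct)$db, st$db)
  expect_error(parse_structure(write_temp_fasta(c("5 x", "1 A 0 2 9 1"))),
               "shorter|malformed")
})

test_that("the fallback folder maximizes pairs (exhaustive check <= 12 nt)", {
  expect_equal(paste(fold_fallback("AAAA")$db, collapse = ""), "....")
  expect_equal(sum(fold_fallback("GGGAAACCC")$pairs > 0) / 2, 3)
  set.seed(14)
  for (trial in 1:40) {
    L <- sample(5:12, 1)
    s <- paste(sample(c("A", "C", "G", "U"), L, TRUE), collapse = "")
    expect_equal(sum(fold_fallback(s)$pairs > 0) / 2, brute_max_pairs(s),
                 info = s)
  }
  ## palindromic 12-mer
  pal <- "GGCGAAAACGCC"
  expect_equal(sum(fold_fallback(pal)$pairs > 0) / 2, brute_max_pairs(pal))
  ## min hairpin loop of 3 is respected
  p <- fold_fallback("GGGGCCCC")$pairs
  opens <- which(p > seq_along(p))
  expect_true(all(p[opens] - opens - 1 >= 3))
})

test_that("four-hairpin structures decompose into the constructed arms", {
  st <- toy_four_helix()
  d <- decompose_helices(st)
  expect_equal(d$helix, c("I", "II", "III", "IV"))
  expect_equal(d$angle, c(0, 90, 180, 270))
  expect_equal(d$stem_length, rep(4, 4))
  expect_equal(d$loop_count, rep(1, 4))
})

test_that("bulges and internal loops are counted along the arm", {
  ## arm with one 5' bulge: 5 bp over two stacked segments + hairpin
  body <- paste0("(((", "A", "((", "AAA", "))", ")))",
                 "A", "((((AAA))))", "A", "((((AAA))))", "A", "((((AAA))))")
  chars <- strsplit(body, "")[[1]]
  st <- secondary_structure(
    paste(ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A")), collapse = ""),
    paste(ifelse(chars %in% c("(", ")"), chars, "."), collapse = ""))
  d <- decompose_helices(st)
  expect_equal(d$stem_length[1], 5)
  expect_equal(d$loop_count[1], 2)  # bulge + hairpin
  expect_equal(d$loop_count[2:4], rep(1, 3))
})

test_that("non-four-armed structures warn, truncate and pad", {
  three <- toy_four_helix()  # rebuild with 3 arms below
  body <- paste0("((((AAA))))", "A", "((((AAA))))", "A", "((((AAA))))")
  chars <- strsplit(body, "")[[1]]
  st3 <- secondary_structure(
    paste(ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A")), collapse = ""),
    paste(ifelse(chars %in% c("(", ")"), chars, "."), collapse = ""))
  expect_warning(d3 <- decompose_helices(st3), "3 helix arms")
  expect_equal(unlist(d3[4, c("angle", "stem_length", "loop_count")],
                      use.names = FALSE), c(0, 0, 0))
  v <- suppressWarnings(feature_vector(st3))
  expect_length(v, 12L)
})

test_that("helix angles follow the equal-arc convention", {
  ## all central-loop unpaired bases between helix IV and the 3' end:
  ## 12 positions of 30 degrees, helices at positions 0,1,2,3
  st <- toy_four_helix(spacers = c(0L, 0L, 0L, 8L))
  expect_equal(unname(helix_angles(st)), c(0, 1, 2, 3) * 30)
  ## hand-evaluated non-uniform spacing: gaps of 1, 2, 3 unpaired bases
  ## between consecutive helices -> positions 0, 2, 5, 9 of 16
  st2 <- toy_four_helix(spacers = c(1L, 2L, 3L, 6L))
  expect_equal(unname(helix_angles(st2)), c(0, 2, 5, 9) * 360 / 16)
})

test_that("angles are invariant under rotation of the exterior-loop start", {
  mk <- function(leading, spacers) {
    arm <- function(z) paste0(strrep("(", z), "AAA", strrep(")", z))
    body <- paste0(strrep("A", leading),
                   arm(4), strrep("A", spacers[1]), arm(4),
                   strrep("A", spacers[2]), arm(4),
                   strrep("A", spacers[3]), arm(4), strrep("A", spacers[4]))
    chars <- strsplit(body, "")[[1]]
    secondary_structure(
      paste(ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A")),
            collapse = ""),
      paste(ifelse(chars %in% c("(", ")"), chars, "."), collapse = ""))
  }
  a1 <- helix_angles(mk(0L, c(1L, 2L, 3L, 6L)))
  a2 <- helix_angles(mk(4L, c(1L, 2L, 3L, 2L)))  # 4 trailing bases moved front
  expect_equal(a1, a2)
})

test_that("feature vectors are equal exactly when structures are equal", {
  st <- toy_four_helix(stems = c(5L, 3L, 6L, 4L), spacers = c(1L, 2L, 0L, 3L))
  st_again <- secondary_structure(paste(st$seq, collapse = ""),
                                  paste(st$db, collapse = ""))
  expect_identical(feature_vector(st, "D. williamsonii")[1:12],
                   feature_vector(st_again, "D. cariniferum")[1:12])
  v <- feature_vector(st, "x")
  expect_named(v, c("angle_I", "angle_II", "angle_III", "angle_IV",
                    "len_I", "len_II", "len_III", "len_IV",
                    "loops_I", "loops_II", "loops_III", "loops_IV"))
})

test_that("an enclosed multibranch loop is found as the central loop", {
  ## one enclosing stem whose loop carries 4 stems
  inner <- paste0("((((AAA))))", "A", "((((AAA))))", "A",
                  "((((AAA))))", "A", "((((AAA))))")
  body <- paste0("(((", inner, ")))")
  chars <- strsplit(body, "")[[1]]
  st <- secondary_structure(
    paste(ifelse(chars == "(", "G", ifelse(chars == ")", "C", "A")), collapse = ""),
    paste(ifelse(chars %in% c("(", ")"), chars, "."), collapse = ""))
  d <- decompose_helices(st)
  expect_equal(d$stem_length, rep(4, 4))
  expect_equal(d$loop_count, rep(1, 4))
})
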