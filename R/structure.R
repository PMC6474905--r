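#' ITS2 secondary structures
#'
#' A `secondary_structure` couples an RNA sequence with a well-nested
#' dot-bracket pairing string of equal length. DNA input is transcribed
#' (T -> U) before structure handling.
#'
#' @param seq nucleotide string (DNA or RNA).
#' @param db dot-bracket string over `.`, `(`, `)`.
#' @param validate check base-pair complementarity (AU/UA, GC/CG, GU/UG) and
#'   minimum hairpin loop of 3; off by default for structures imported from
#'   external predictors.
#' @return object of class `secondary_structure` with fields `seq`, `db`,
#'   `pairs` (integer vector, 0 = unpaired).
#' @export
secondary_structure <- function(seq, db, validate = FALSE) {
  seq <- check_nucleotides(seq, rna = TRUE)
  seq[seq == "T"] <- "U"
  if (length(db) == 1L) db <- strsplit(db, "")[[1]]
  fail_if(length(seq) != length(db),
          "sequence (%d) and structure (%d) lengths differ",
          length(seq), length(db))
  bad <- which(!db %in% c(".", "(", ")"))
  if (length(bad)) {
    fail_if(db[bad[1]] %in% c("[", "]", "{", "}", "<", ">"),
            "pseudoknot notation '%s' at position %d not supported",
            db[bad[1]], bad[1])
    fail_if(TRUE, "invalid structure character '%s' at position %d",
            db[bad[1]], bad[1])
  }
  pairs <- integer(length(db))
  stack <- integer(0)
  for (i in seq_along(db)) {
    if (db[i] == "(") stack <- c(stack, i)
    else if (db[i] == ")") {
      fail_if(length(stack) == 0L, "unbalanced ')' at position %d", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j; pairs[j] <- i
    }
  }
  fail_if(length(stack) > 0L, "unbalanced '(' at position %d", stack[1])
  if (validate) {
    ok_pairs <- c("AU", "UA", "GC", "CG", "GU", "UG")
    for (i in which(pairs > seq_along(pairs))) {
      j <- pairs[i]
      fail_if(!paste0(seq[i], seq[j]) %in% ok_pairs,
              "non-complementary pair %s-%s at %d-%d", seq[i], seq[j], i, j)
      fail_if(j - i - 1L < 3L && all(pairs[(i + 1L):(j - 1L)] == 0L),
              "hairpin loop shorter than 3 at pair %d-%d", i, j)
    }
  }
  structure(list(seq = seq, db = db, pairs = pairs),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("<secondary_structure> %d nt, %d pairs\n",
              length(x$seq), sum(x$pairs > 0) / 2))
  invisible(x)
}

#' Parse a secondary structure from Vienna dot-bracket or CT format
#'
#' Vienna (`.fold`/`.db`): optional `>header` line, sequence line, structure
#' line. CT: header line with the sequence length, then one line per base
#' (`i base i-1 i+1 pair index`), converted losslessly to dot-bracket.
#'
#' @param path input file.
#' @param format `"auto"` (detect), `"vienna"` or `"ct"`.
#' @param validate passed to [secondary_structure()].
#' @return a `secondary_structure` (with attribute `id` if a header names it).
#' @export
parse_structure <- function(path, format = c("auto", "vienna", "ct"),
                            validate = FALSE) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fail_if(length(lines) == 0L, "empty structure file: %s", path)
  if (format == "auto") {
    format <- if (grepl("^>", lines[1]) ||
                  grepl("^[ACGTUNacgtun]+$", trimws(lines[1]))) "vienna" else "ct"
  }
  if (format == "vienna") {
    id <- NA_character_
    if (grepl("^>", lines[1])) {
      id <- sub("^>", "", lines[1]); lines <- lines[-1]
    }
    fail_if(length(lines) < 2L, "vienna input needs sequence and structure lines")
    st <- secondary_structure(trimws(lines[1]),
                              sub("\\s+.*$", "", trimws(lines[2])),
                              validate = validate)
    attr(st, "id") <- id
    return(st)
  }
  ## CT
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- suppressWarnings(as.integer(hdr[1]))
  fail_if(is.na(n), "CT header does not start with the sequence length")
  fail_if(length(lines) < n + 1L, "CT file shorter than header length %d", n)
  seq <- character(n); prt <- integer(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    fail_if(length(f) < 6L, "malformed CT line %d", i + 1L)
    seq[i] <- f[2]; prt[i] <- as.integer(f[5])
  }
  db <- rep(".", n)
  db[prt > seq_len(n)] <- "("
  db[prt > 0L & prt < seq_len(n)] <- ")"
  st <- secondary_structure(seq, db, validate = validate)
  fail_if(!identical(st$pairs, prt), "CT pairing is not well-nested")
  st
}

#' Write a structure in Vienna dot-bracket format
#'
#' @param structure a `secondary_structure`.
#' @param path output file.
#' @param id header label.
#' @export
write_vienna <- function(structure, path, id = attr(structure, "id") %||% "structure") {
  writeLines(c(paste0(">", id), seq_string(structure$seq),
               seq_string(structure$db)), path)
  invisible(path)
}

#' Maximum base-pairing fallback folder
#'
#' Nussinov-style dynamic programming maximizing the number of nested
#' base pairs (AU/UA, GC/CG, GU/UG) with a minimum hairpin loop of 3 and a
#' deterministic traceback (pairing preferred over leaving a base unpaired;
#' the leftmost pairing partner is taken first). A crude stand-in for a real
#' structure predictor, sufficient for exercising the feature pipeline.
#'
#' @param seq nucleotide string (DNA accepted; transcribed to RNA).
#' @return a `secondary_structure`.
#' @export
fold_fallback <- function(seq) {
  seq <- check_nucleotides(seq, rna = TRUE)
  seq[seq == "T"] <- "U"
  n <- length(seq)
  fail_if(n < 1L || n > 2000L, "sequence length %d outside [1, 2000]", n)
  can_pair <- function(x, y) {
    paste0(x, y) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
  }
  P <- outer(seq, seq, can_pair)
  N <- matrix(0L, n, n)
  if (n >= 5L) {
    for (span in 4L:(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i + 1L, j]                       # i unpaired
        ks <- (i + 4L):j
        ks <- ks[P[i, ks]]
        if (length(ks)) {
          inner <- ifelse(ks - 1L >= i + 1L, N[cbind(i + 1L, ks - 1L)], 0L)
          outer_ <- ifelse(ks + 1L <= j, N[cbind(pmin(ks + 1L, j), j)], 0L)
          outer_[ks + 1L > j] <- 0L
          best <- max(best, max(inner + outer_ + 1L))
        }
        N[i, j] <- best
      }
    }
  }
  db <- rep(".", n)
  ## deterministic traceback: prefer pairing, leftmost partner first
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    if (i >= j || j - i < 4L) next
    target <- N[i, j]
    if (target == 0L) next
    paired <- FALSE
    ks <- (i + 4L):j
    ks <- ks[P[i, ks]]
    for (k in ks) {
      inner <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
      outer_ <- if (k + 1L <= j) N[k + 1L, j] else 0L
      if (inner + outer_ + 1L == target) {
        db[i] <- "("; db[k] <- ")"
        if (k - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  secondary_structure(seq, db)
}

## Children (outermost pairs) of the loop spanning [lo, hi] given pairing p.
scan_children <- function(p, lo, hi) {
  out <- list()
  i <- lo
  while (i <= hi) {
    if (p[i] > i) {
      out[[length(out) + 1L]] <- c(i, p[i])
      i <- p[i] + 1L
    } else i <- i + 1L
  }
  out
}

total_pairs <- function(p, i, j) { idx <- i:j; sum(p[idx] > idx) }

## Stats of one arm rooted at pair (i, j): base pairs along the main stack
## path and loop count (bulges + internal loops + multibranch openings along
## the path + the terminal hairpin).
arm_stats <- function(p, i, j) {
  stem <- 0L; loops <- 0L
  repeat {
    stem <- stem + 1L
    while (i + 1L < j - 1L && p[i + 1L] == j - 1L) {
      i <- i + 1L; j <- j - 1L; stem <- stem + 1L
    }
    kids <- if (i + 1L <= j - 1L) scan_children(p, i + 1L, j - 1L) else list()
    loops <- loops + 1L                     # hairpin, bulge/internal, or multibranch
    if (length(kids) == 0L) break           # terminal hairpin
    if (length(kids) == 1L) {
      i <- kids[[1]][1]; j <- kids[[1]][2]
    } else {
      sizes <- vapply(kids, function(k) total_pairs(p, k[1], k[2]), numeric(1))
      main <- kids[[which.max(sizes)]]      # largest sub-stack; first on ties
      i <- main[1]; j <- main[2]
    }
  }
  c(stem_length = stem, loop_count = loops)
}

## Locate the central loop: the exterior loop if >= 2 stems emanate from it,
## otherwise descend through unbranched stems to the first multibranch loop.
## Returns list(arms = list of (i, j) pairs, n_positions = total equal-arc
## positions on the loop, arm_pos = 0-based position index of each arm).
central_loop <- function(st) {
  p <- st$pairs
  n <- length(p)
  enclosing <- NULL
  lo <- 1L; hi <- n
  kids <- scan_children(p, lo, hi)
  if (length(kids) == 1L) {
    ## single stem at the exterior: descend unbranched stems/bulges until a
    ## multibranch loop appears; a plain hairpin keeps the exterior loop
    i <- kids[[1]][1]; j <- kids[[1]][2]
    repeat {
      while (i + 1L < j - 1L && p[i + 1L] == j - 1L) { i <- i + 1L; j <- j - 1L }
      inner <- if (i + 1L <= j - 1L) scan_children(p, i + 1L, j - 1L) else list()
      if (length(inner) >= 2L) {
        enclosing <- c(i, j); lo <- i + 1L; hi <- j - 1L
        break
      }
      if (length(inner) == 0L) break
      i <- inner[[1]][1]; j <- inner[[1]][2]
    }
  }
  ## walk the central loop 5'->3': unpaired positions and stem attachments
  pos <- 0L
  arm_pos <- integer(0)
  arms <- list()
  i <- lo
  while (i <= hi) {
    if (p[i] > i) {
      arms[[length(arms) + 1L]] <- c(i, p[i])
      arm_pos <- c(arm_pos, pos)
      pos <- pos + 1L
      i <- p[i] + 1L
    } else {
      pos <- pos + 1L
      i <- i + 1L
    }
  }
  if (!is.null(enclosing)) pos <- pos + 1L  # the enclosing stem occupies arc too
  list(arms = arms, n_positions = pos, arm_pos = arm_pos)
}

#' Decompose a structure into its helix arms
#'
#' Identifies the central (multibranch or exterior) loop and treats each
#' emanating stem plus everything distal to it as one arm, numbered I-IV in
#' 5'->3' order of attachment. Warns when the arm count differs from the
#' canonical four: extra arms are truncated, missing arms padded with
#' `(0, 0, 0)`.
#'
#' @param structure a `secondary_structure`.
#' @return data.frame with columns `helix` (I-IV), `angle` (degrees),
#'   `stem_length`, `loop_count`.
#' @export
decompose_helices <- function(structure) {
  cl <- central_loop(structure)
  k <- length(cl$arms)
  if (k != 4L) {
    warning(sprintf("structure has %d helix arms, expected 4 (%s)", k,
                    if (k > 4L) "extra arms truncated" else "missing arms padded"),
            call. = FALSE)
  }
  use <- seq_len(min(k, 4L))
  stats <- t(vapply(cl$arms[use], function(a) arm_stats(structure$pairs, a[1], a[2]),
                    numeric(2)))
  angles <- (cl$arm_pos[use] - cl$arm_pos[1]) %% cl$n_positions *
    (360 / cl$n_positions)
  out <- data.frame(helix = c("I", "II", "III", "IV"),
                    angle = 0, stem_length = 0, loop_count = 0)
  out$angle[use] <- angles
  out$stem_length[use] <- stats[, "stem_length"]
  out$loop_count[use] <- stats[, "loop_count"]
  out
}

#' Helix angles under the equal-arc radial layout
#'
#' Walking the central loop 5'->3', every position (unpaired base or helix
#' attachment) occupies an equal arc of 360 degrees; a helix's angle is the
#' arc position of its attachment, with Helix I anchored at 0.
#'
#' @param structure a `secondary_structure`.
#' @return numeric vector of 4 angles in degrees (absent helices 0).
#' @export
helix_angles <- function(structure) {
  d <- suppressWarnings(decompose_helices(structure))
  setNames(d$angle, d$helix)
}

#' Fixed-order 12-element ITS2 feature vector
#'
#' `[angle I-IV, stem length I-IV, loop count I-IV]`; absent helices are
#' encoded as zeros.
#'
#' @param structure a `secondary_structure`.
#' @param taxon id attached as attribute `taxon`.
#' @return named numeric vector of length 12.
#' @export
feature_vector <- function(structure, taxon = NA_character_) {
  d <- suppressWarnings(decompose_helices(structure))
  v <- c(d$angle, d$stem_length, d$loop_count)
  names(v) <- c(paste0("angle_", d$helix), paste0("len_", d$helix),
                paste0("loops_", d$helix))
  attr(v, "taxon") <- taxon
  v
}

#' Feature table for a set of structures
#'
#' @param structures named list of `secondary_structure`s.
#' @return matrix (taxa x 12 features).
#' @export
feature_table <- function(structures) {
  fail_if(length(structures) == 0L, "no structures")
  rows <- lapply(names(structures), function(nm) {
    feature_vector(structures[[nm]], nm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(structures)
  out
}
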