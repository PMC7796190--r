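## Hammerhead-specific sequence logic: GUC|N cleavage-site scanning, the
## three-helix pairing topology (H1: substrate 3'-flank x ribozyme 5'-arm,
## H3: substrate 5'-flank x ribozyme 3'-arm, H2: intramolecular stem closing
## a 4-nt loop in the ribozyme core), and heavy-atom accounting.

#' Find hammerhead cleavage sites in a substrate sequence
#'
#' Scans for the GUC motif followed by at least one nucleotide (GUC|N);
#' cleavage occurs 3' of the C. Returned positions are the 1-based index of
#' the C of each motif.
#'
#' @param seq substrate sequence (A/C/G/U).
#' @return integer vector of positions (possibly empty).
#' @export
find_cleavage_sites <- function(seq) {
  s <- check_sequence(seq)
  n <- length(s)
  hits <- integer(0)
  for (i in seq_len(max(0, n - 3))) {
    if (s[i] == "G" && s[i + 1] == "U" && s[i + 2] == "C") {
      hits <- c(hits, i + 2L)
    }
  }
  hits
}

complementary <- function(a, b) b == chartr("ACGU", "UGCA", a)

new_pair <- function(chain1, resi1, resn1, chain2, resi2, resn2, helix) {
  type <- paste(sort(c(resn1, resn2), decreasing = TRUE), collapse = "-")
  if (!type %in% c("G-C", "U-A")) type <- "other"
  if (type == "U-A") type <- "A-U"
  data.frame(chain1 = chain1, resi1 = resi1, resn1 = resn1,
             chain2 = chain2, resi2 = resi2, resn2 = resn2,
             type = type, helix = helix, stringsAsFactors = FALSE)
}

#' Derive the hammerhead pairing topology from the two sequences
#'
#' Helix 1 pairs the substrate 3'-flank with the ribozyme 5'-arm (anchored
#' at the ribozyme 5' terminus against the substrate 3' terminus), helix 3
#' pairs the substrate 5'-flank with the ribozyme 3'-arm (anchored at the
#' ribozyme 3' terminus, slid over the flank for the maximal complementary
#' run), and helix 2 is the maximal intramolecular complementary stem
#' closing a 4-nt loop inside the ribozyme core. Remaining core residues
#' are recorded as unpaired; the (unique) GUC|N cleavage site is recorded.
#'
#' @param ribozyme_seq 5'-3' ribozyme sequence.
#' @param substrate_seq 5'-3' substrate sequence containing exactly one
#'   GUC|N site.
#' @param chains chain ids of (ribozyme, substrate) used in pair references.
#' @param loop_len loop length closed by the intramolecular stem (4 for the
#'   GAAA tetraloop hammerhead).
#' @return object of class `pairing_map`: list with `pairs` (data frame,
#'   columns chain1/resi1/resn1/chain2/resi2/resn2/type/helix), `unpaired`
#'   (data frame chain/resi), `cleavage_site`, and the input sequences.
#' @export
hammerhead_pairing <- function(ribozyme_seq, substrate_seq,
                               chains = c("R", "S"), loop_len = 4L) {
  rz <- check_sequence(ribozyme_seq)
  sub <- check_sequence(substrate_seq)
  nr <- length(rz); ns <- length(sub)
  sites <- find_cleavage_sites(substrate_seq)
  if (length(sites) != 1) {
    stop("topology error: expected exactly one GUC|N site, found ",
         length(sites))
  }
  site <- sites[1]
  ## helix 1: (rz 1+t) x (sub ns-t), anchored at both termini
  if (!complementary(rz[1], sub[ns])) {
    stop("topology error: helix 1 anchor mismatch at ribozyme 1 / substrate ",
         ns, " (", rz[1], " vs ", sub[ns], ")")
  }
  h1 <- 0L
  while (1 + h1 <= nr && ns - h1 > site && complementary(rz[1 + h1], sub[ns - h1])) {
    h1 <- h1 + 1L
  }
  if (h1 < 2) stop("topology error: helix 1 shorter than 2 pairs")
  pairs <- lapply(seq_len(h1) - 1L, function(t) {
    new_pair(chains[1], 1 + t, rz[1 + t], chains[2], ns - t, sub[ns - t], "H1")
  })
  ## helix 3: (rz nr-t) x (sub j0+t), anchored at the ribozyme 3' end,
  ## slid over the substrate 5' flank for the maximal run
  best <- NULL
  for (j0 in seq_len(site - 1L)) {
    L <- 0L
    while (nr - L > 0 && j0 + L < site && complementary(rz[nr - L], sub[j0 + L])) {
      L <- L + 1L
    }
    if (is.null(best) || L > best$L) best <- list(j0 = j0, L = L)
  }
  if (is.null(best) || best$L < 2) {
    mism <- vapply(seq_len(min(site - 1, nr)), function(t) {
      !complementary(rz[nr - t + 1], sub[t])
    }, logical(1))
    stop("topology error: no helix 3 complementary run; mismatches at substrate ",
         paste(which(mism), collapse = ", "))
  }
  pairs <- c(pairs, lapply(seq_len(best$L) - 1L, function(t) {
    new_pair(chains[1], nr - t, rz[nr - t], chains[2], best$j0 + t,
             sub[best$j0 + t], "H3")
  }))
  ## helix 2: maximal complementary stem closing a loop of loop_len within
  ## the ribozyme core (between the two arms)
  core_lo <- h1 + 1L
  core_hi <- nr - best$L
  h2 <- NULL
  for (s0 in core_lo:core_hi) {
    for (L in seq_len((core_hi - core_lo + 1L - loop_len) %/% 2)) {
      e0 <- s0 + 2L * L + loop_len - 1L
      if (e0 > core_hi) break
      ok <- all(vapply(seq_len(L) - 1L, function(t) {
        complementary(rz[s0 + t], rz[e0 - t])
      }, logical(1)))
      if (ok && (is.null(h2) || L > h2$L)) h2 <- list(s0 = s0, e0 = e0, L = L)
    }
  }
  if (is.null(h2)) stop("topology error: no intramolecular stem found in core")
  pairs <- c(pairs, lapply(seq_len(h2$L) - 1L, function(t) {
    new_pair(chains[1], h2$s0 + t, rz[h2$s0 + t], chains[1], h2$e0 - t,
             rz[h2$e0 - t], "H2")
  }))
  pairs <- do.call(rbind, pairs)
  paired_rz <- c(pairs$resi1[pairs$chain1 == chains[1]],
                 pairs$resi2[pairs$chain2 == chains[1]])
  paired_sub <- c(pairs$resi1[pairs$chain1 == chains[2]],
                  pairs$resi2[pairs$chain2 == chains[2]])
  unpaired <- rbind(
    data.frame(chain = chains[1], resi = setdiff(seq_len(nr), paired_rz)),
    data.frame(chain = chains[2], resi = setdiff(seq_len(ns), paired_sub)))
  loop <- (h2$s0 + h2$L):(h2$e0 - h2$L)
  structure(list(pairs = pairs, unpaired = unpaired,
                 cleavage_site = site,
                 loop = loop,
                 chains = chains,
                 ribozyme_seq = ribozyme_seq, substrate_seq = substrate_seq),
            class = "pairing_map")
}

#' @export
print.pairing_map <- function(x, ...) {
  cat("<pairing_map> cleavage site at substrate position ", x$cleavage_site,
      "\n", sep = "")
  for (h in unique(x$pairs$helix)) {
    p <- x$pairs[x$pairs$helix == h, ]
    cat("  ", h, ": ", nrow(p), " pairs (",
        paste0(p$resn1, "-", p$resn2, collapse = ","), ")\n", sep = "")
  }
  cat("  unpaired: ", nrow(x$unpaired), " residues\n", sep = "")
  invisible(x)
}

#' Dot-bracket representation of a pairing map
#'
#' Two-chain dialect: ribozyme then substrate, separated by `&`.
#'
#' @param map a `pairing_map`.
#' @return character scalar.
#' @export
pairing_to_dotbracket <- function(map) {
  nr <- nchar(map$ribozyme_seq); ns <- nchar(map$substrate_seq)
  rz <- rep(".", nr); sub <- rep(".", ns)
  for (k in seq_len(nrow(map$pairs))) {
    p <- map$pairs[k, ]
    if (p$chain1 == map$chains[1] && p$chain2 == map$chains[1]) {
      rz[p$resi1] <- "("; rz[p$resi2] <- ")"
    } else {
      rz[if (p$chain1 == map$chains[1]) p$resi1 else p$resi2] <- "("
      sub[if (p$chain1 == map$chains[2]) p$resi1 else p$resi2] <- ")"
    }
  }
  paste0(paste(rz, collapse = ""), "&", paste(sub, collapse = ""))
}

#' Template-based heavy-atom count of a selection
#'
#' Counts heavy atoms from the residue templates (base atoms plus 12
#' backbone atoms with a 5'-phosphate, 9 for a free 5'-OH terminal
#' residue), honouring each chain's 5'-terminus policy.
#'
#' @param seqs character vector of chain sequences.
#' @param five_prime_phosphate logical vector (recycled): does each chain
#'   start with a 5'-phosphate? Default `FALSE` (free 5'-OH).
#' @return integer heavy-atom count.
#' @export
count_heavy_atoms <- function(seqs, five_prime_phosphate = FALSE) {
  five_prime_phosphate <- rep_len(five_prime_phosphate, length(seqs))
  total <- 0L
  for (k in seq_along(seqs)) {
    s <- check_sequence(seqs[k])
    for (i in seq_along(s)) {
      total <- total + template_atom_count(
        s[i], five_prime_phosphate = i > 1 || five_prime_phosphate[k])
    }
  }
  total
}
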