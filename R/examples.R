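# Bundled synthetic example data. The alignment emitted here is an
# invented, clearly-labelled stand-in for a Rho-family GTPase alignment:
# sequence content is pseudo-random around a shared core, with a charged
# alpha-I/alpha-4 interface window and short, basic C-terminal tails for
# the short-tail members. It exists so that examples and tests exercise
# the census machinery without fetching real sequences.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

synthetic_core <- function(len) {
  # deterministic pseudo-random core shared by all synthetic sequences
  idx <- ((7919 * seq_len(len) + 104729) %% 97) %% 20 + 1
  paste(AA20[idx], collapse = "")
}

apply_subs <- function(seq, subs) {
  ch <- strsplit(seq, "")[[1]]
  for (pos in names(subs)) ch[as.integer(pos)] <- subs[[pos]]
  paste(ch, collapse = "")
}

#' Write the bundled synthetic Rho-family example alignment
#'
#' Emits a small aligned FASTA of nine invented Rho-family-like sequences
#' (ids `RHOD`, `RND1`, `RAC1`, `RHOA`, `CDC42`, `RIF`, `RND3`, `RHBT1`,
#' `RHBT2`) sharing a 180-residue catalytic core with sequence variation in
#' the membrane-interface window (reference residues 130-146 and 150-160)
#' and C-terminal tails of differing lengths, gap-padded to equal width.
#' Entirely synthetic: the census examples need plausible structure, not
#' real sequences. Short-tail members carry more basic interface residues,
#' mirroring the charge/tail-length correlation the census is built to
#' expose.
#'
#' @param path output FASTA path.
#' @return invisibly, `path`.
#' @export
write_example_alignment <- function(path) {
  core <- synthetic_core(180)
  spec <- list(
    RHOD  = list(subs = list(`133` = "K", `137` = "R", `144` = "R",
                             `145` = "R", `154` = "H", `155` = "R",
                             `158` = "K"),
                 tail = "RRSKCFS"),
    RND1  = list(subs = list(`133` = "L", `138` = "E", `140` = "S",
                             `144` = "D", `150` = "E", `154` = "Q",
                             `155` = "S"),
                 tail = "SSQNSSKSLMSRGRSAGSERSHHGNQ"),
    RAC1  = list(subs = list(`133` = "Q", `144` = "E", `154` = "N",
                             `155` = "T"),
                 tail = "APNVPIILVGNKKDLESTRAVS"),
    RHOA  = list(subs = list(`133` = "T", `144` = "D", `154` = "S",
                             `155` = "E"),
                 tail = "GSQNGCINCCKVLSA"),
    CDC42 = list(subs = list(`133` = "K", `144` = "R", `154` = "K",
                             `155` = "R"),
                 tail = "KKSRRCVL"),
    RIF   = list(subs = list(`133` = "S", `144` = "E", `154` = "D",
                             `155` = "N"),
                 tail = "QQSTGEKSSNCCAIMNGQGVD"),
    RND3  = list(subs = list(`133` = "A", `138` = "E", `144` = "E",
                             `154` = "S", `155` = "D"),
                 tail = "SSHTDLHLASQSNGSKSTDRSAQGSGSEVHS"),
    RHBT1 = list(subs = list(`133` = "R", `144` = "K", `154` = "R",
                             `155` = "K"),
                 tail = "KRSGCF"),
    RHBT2 = list(subs = list(`133` = "K", `144` = "R", `154` = "K",
                             `155` = "H"),
                 tail = "RKSAC"))
  tails <- vapply(spec, function(x) x$tail, character(1))
  width <- 180 + max(nchar(tails))
  lines <- character(0)
  for (id in names(spec)) {
    seq <- paste0(apply_subs(core, spec[[id]]$subs), spec[[id]]$tail)
    seq <- paste0(seq, strrep("-", width - nchar(seq)))
    lines <- c(lines, paste0(">", id), seq)
  }
  writeLines(lines, path)
  invisible(path)
}
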