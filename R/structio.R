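#' @useDynLib memtether, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---------------------------------------------------------------------------
# Domain containers: Structure, Trajectory, AtomIndexSet
# ---------------------------------------------------------------------------

#' Construct a Structure
#'
#' A `Structure` holds an ordered atom table and an optional orthorhombic box.
#' Atom order is stable and is the indexing frame for every selection and
#' every trajectory frame.
#'
#' @param atoms data.frame with columns `serial` (unique positive integer),
#'   `name` (atom name), `element`, `resname` (3-4 character residue name),
#'   `resid` (author residue numbering, 1-based), `chain` (single character),
#'   `x`, `y`, `z` (Angstrom). Extra columns are preserved.
#' @param box numeric length-3 box lengths in Angstrom, or `NULL`.
#' @return object of class `Structure`.
#' @export
new_structure <- function(atoms, box = NULL) {
  req <- c("serial", "name", "element", "resname", "resid", "chain",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("empty input: structure has zero atoms")
  if (anyDuplicated(atoms$serial)) stop("atom serial numbers must be unique")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  if (!is.null(box)) {
    box <- as.numeric(box)
    if (length(box) != 3L || !all(is.finite(box)) || any(box <= 0)) {
      stop("box must be three positive finite lengths (Angstrom)")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, box = box), class = "Structure")
}

#' @export
print.Structure <- function(x, ...) {
  cat(sprintf("Structure: %d atoms, %d residues%s\n",
              nrow(x$atoms),
              nrow(unique(x$atoms[, c("chain", "resid")])),
              if (is.null(x$box)) "" else
                sprintf(", box %.1f x %.1f x %.1f A",
                        x$box[1], x$box[2], x$box[3])))
  invisible(x)
}

#' Number of atoms in a Structure
#' @param s a `Structure`.
#' @return integer atom count.
#' @export
n_atoms <- function(s) nrow(s$atoms)

#' Coordinates of a Structure as an N x 3 matrix
#' @param s a `Structure`.
#' @return numeric N x 3 matrix (Angstrom).
#' @export
coords <- function(s) unname(as.matrix(s$atoms[, c("x", "y", "z")]))

#' Construct a Trajectory
#'
#' Ordered coordinate frames over a fixed topology. Every frame must carry
#' exactly as many coordinate rows as the topology has atoms, and times must
#' be strictly increasing.
#'
#' @param topology a `Structure`.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @param frames list of N x 3 coordinate matrices (Angstrom).
#' @param box optional per-trajectory box override (defaults to the
#'   topology box).
#' @return object of class `Trajectory`.
#' @export
new_trajectory <- function(topology, times, frames, box = topology$box) {
  if (!inherits(topology, "Structure")) stop("topology must be a Structure")
  if (length(times) != length(frames)) {
    stop("times and frames must have equal length")
  }
  if (length(frames) == 0L) stop("empty input: trajectory has zero frames")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  na <- n_atoms(topology)
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || nrow(fr) != na || ncol(fr) != 3L) {
      stop(sprintf("structural mismatch: frame %d has %s coordinates; topology has %d atoms",
                   i, if (is.matrix(fr)) nrow(fr) else "invalid", na))
    }
    if (!all(is.finite(fr))) stop(sprintf("frame %d has non-finite coordinates", i))
    frames[[i]] <- unname(fr)
  }
  structure(list(topology = topology, times = as.numeric(times),
                 frames = frames, box = box),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames x %d atoms, t = %.4g .. %.4g ns\n",
              length(x$frames), n_atoms(x$topology),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a Trajectory
#' @param traj a `Trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(traj) length(traj$frames)

# ---------------------------------------------------------------------------
# PDB reading
# ---------------------------------------------------------------------------

# Fixed-column PDB ATOM/HETATM field extraction with validation.
# Returns a data.frame of atoms; errors name the offending input line.
parse_pdb_atoms <- function(lines, line_numbers) {
  n <- length(lines)
  if (n == 0L) stop("empty input: no ATOM/HETATM records found")
  field <- function(from, to) substr(lines, from, to)
  serial  <- suppressWarnings(as.integer(trimws(field(7, 11))))
  name    <- trimws(field(13, 16))
  altloc  <- field(17, 17)
  resname <- trimws(field(18, 21))
  chain   <- field(22, 22)
  resid   <- suppressWarnings(as.integer(trimws(field(23, 26))))
  icode   <- field(27, 27)
  xs <- trimws(field(31, 38)); ys <- trimws(field(39, 46)); zs <- trimws(field(47, 54))
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  element <- trimws(field(77, 78))

  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z) |
                 xs == "" | ys == "" | zs == "")
  if (length(bad) > 0L) {
    stop(sprintf("malformed coordinate field at line %d: '%s'",
                 line_numbers[bad[1]], lines[bad[1]]))
  }
  bad <- which(is.na(serial) | is.na(resid))
  if (length(bad) > 0L) {
    stop(sprintf("malformed serial/residue field at line %d: '%s'",
                 line_numbers[bad[1]], lines[bad[1]]))
  }
  bad <- which(icode != " " & icode != "")
  if (length(bad) > 0L) {
    stop(sprintf("insertion codes are not supported (line %d)",
                 line_numbers[bad[1]]))
  }

  # first altloc kept: drop any located record duplicating an earlier record
  # of the same (chain, resid, name)
  has_alt <- altloc != " " & altloc != ""
  if (any(has_alt)) {
    key <- paste(chain, resid, name, sep = "\r")
    drop <- has_alt & duplicated(key)
    keep <- !drop
    serial <- serial[keep]; name <- name[keep]; resname <- resname[keep]
    chain <- chain[keep]; resid <- resid[keep]
    x <- x[keep]; y <- y[keep]; z <- z[keep]; element <- element[keep]
  }

  # infer element from the atom name when the element column is absent
  no_el <- element == ""
  if (any(no_el)) {
    guess <- sub("^[0-9]*", "", name[no_el])
    element[no_el] <- toupper(substr(guess, 1, 1))
  }
  data.frame(serial = serial, name = name, element = element,
             resname = resname, resid = resid, chain = chain,
             x = x, y = y, z = z, stringsAsFactors = FALSE)
}

parse_cryst1 <- function(line) {
  a <- suppressWarnings(as.numeric(substr(line, 7, 15)))
  b <- suppressWarnings(as.numeric(substr(line, 16, 24)))
  c_ <- suppressWarnings(as.numeric(substr(line, 25, 33)))
  if (any(!is.finite(c(a, b, c_)))) stop("malformed CRYST1 record")
  c(a, b, c_)
}

# Split raw PDB lines into per-model atom record blocks. Returns a list with
# one element per MODEL (or a single element when no MODEL records exist);
# each element holds $lines and $line_numbers.
split_pdb_models <- function(lines) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) == 0L) {
    idx <- which(is_atom)
    return(list(list(lines = lines[idx], line_numbers = idx)))
  }
  model_ends <- which(startsWith(lines, "ENDMDL"))
  out <- vector("list", length(model_starts))
  for (m in seq_along(model_starts)) {
    from <- model_starts[m]
    to <- if (m <= length(model_ends)) model_ends[m] else length(lines)
    idx <- which(is_atom & seq_along(lines) > from & seq_along(lines) < to + 1L)
    out[[m]] <- list(lines = lines[idx], line_numbers = idx,
                     block = lines[from:min(to, length(lines))])
  }
  out
}

is_frame_format <- function(first_line) {
  grepl("^\\s*[0-9]+\\s+[0-9]+\\s*$", first_line)
}

#' Read a structure from PDB or the plain-text frame format
#'
#' PDB `ATOM`/`HETATM`/`MODEL`/`CRYST1` records are supported; the first
#' MODEL is used as the topology and `CRYST1` is parsed into the box.
#' Residue numbering is PDB author numbering (1-based). The first alternate
#' location of an atom is kept; insertion codes are rejected.
#'
#' The plain-text frame format (see [write_frames()]) carries no atom
#' metadata; generic atom records (name `BD`, element `X`, chain `A`,
#' one residue per atom) are synthesized for it.
#'
#' @param path file path.
#' @return a [new_structure()] `Structure`.
#' @export
read_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty input: ", path)
  if (is_frame_format(lines[1])) {
    ff <- parse_frame_file(lines)
    na <- nrow(ff$frames[[1]])
    atoms <- data.frame(serial = seq_len(na), name = "BD", element = "X",
                        resname = "BEA", resid = seq_len(na), chain = "A",
                        x = ff$frames[[1]][, 1], y = ff$frames[[1]][, 2],
                        z = ff$frames[[1]][, 3], stringsAsFactors = FALSE)
    return(new_structure(atoms))
  }
  box <- NULL
  cl <- which(startsWith(lines, "CRYST1"))
  if (length(cl) > 0L) box <- parse_cryst1(lines[cl[1]])
  models <- split_pdb_models(lines)
  first <- models[[1]]
  atoms <- parse_pdb_atoms(first$lines, first$line_numbers)
  new_structure(atoms, box = box)
}

#' Read a trajectory from multi-model PDB or the plain-text frame format
#'
#' One frame is produced per `MODEL`. Frame times are taken from embedded
#' `REMARK ... TIME <t>` records when present, otherwise they default to
#' `frame index x stride` ns (the saving stride of the source simulation is
#' configuration, never inferred).
#'
#' @param path file path.
#' @param topology `Structure` the frames must match atom-for-atom.
#' @param stride time per frame in ns used when the file embeds no times.
#' @return a [new_trajectory()] `Trajectory`.
#' @export
read_trajectory <- function(path, topology, stride = 1) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty input: ", path)
  na <- n_atoms(topology)
  if (is_frame_format(lines[1])) {
    ff <- parse_frame_file(lines)
    for (i in seq_along(ff$frames)) {
      if (nrow(ff$frames[[i]]) != na) {
        stop(sprintf("structural mismatch: frame %d has %d atoms; topology has %d",
                     i, nrow(ff$frames[[i]]), na))
      }
    }
    return(new_trajectory(topology, ff$times, ff$frames))
  }
  models <- split_pdb_models(lines)
  frames <- vector("list", length(models))
  times <- rep(NA_real_, length(models))
  for (m in seq_along(models)) {
    at <- parse_pdb_atoms(models[[m]]$lines, models[[m]]$line_numbers)
    if (nrow(at) != na) {
      stop(sprintf("structural mismatch in model %d: %d atoms, topology has %d",
                   m, nrow(at), na))
    }
    frames[[m]] <- unname(as.matrix(at[, c("x", "y", "z")]))
    blk <- models[[m]]$block
    if (!is.null(blk)) {
      tl <- grep("^REMARK.*\\bTIME\\b", blk, value = TRUE)
      if (length(tl) > 0L) {
        tv <- regmatches(tl[1], regexpr("[-+0-9.eE]+\\s*(NS)?\\s*$", tl[1]))
        tv <- suppressWarnings(as.numeric(sub("NS\\s*$", "", trimws(tv))))
        if (is.finite(tv)) times[m] <- tv
      }
    }
  }
  if (anyNA(times)) times <- (seq_along(frames) - 1) * stride
  new_trajectory(topology, times, frames)
}

parse_frame_file <- function(lines) {
  hdr <- scan(text = lines[1], what = integer(), quiet = TRUE)
  na <- hdr[1]; nf <- hdr[2]
  if (na <= 0L || nf <= 0L) stop("frame format header must be 'natoms nframes' with positive counts")
  need <- 1L + nf * (na + 1L)
  if (length(lines) < need) {
    stop(sprintf("frame file truncated: expected %d lines, found %d", need, length(lines)))
  }
  frames <- vector("list", nf)
  times <- numeric(nf)
  at <- 2L
  for (f in seq_len(nf)) {
    t <- suppressWarnings(as.numeric(trimws(lines[at])))
    if (!is.finite(t)) stop(sprintf("malformed time at line %d", at))
    times[f] <- t
    xyz <- matrix(NA_real_, na, 3)
    for (i in seq_len(na)) {
      v <- suppressWarnings(scan(text = lines[at + i], what = double(),
                                 quiet = TRUE))
      if (length(v) != 3L || !all(is.finite(v))) {
        stop(sprintf("malformed coordinate field at line %d: '%s'",
                     at + i, lines[at + i]))
      }
      xyz[i, ] <- v
    }
    frames[[f]] <- xyz
    at <- at + na + 1L
  }
  list(times = times, frames = frames)
}

# ---------------------------------------------------------------------------
# PDB / frame-format writing
# ---------------------------------------------------------------------------

format_pdb_atom_lines <- function(atoms, xyz) {
  name <- ifelse(nchar(atoms$name) < 4L, paste0(" ", atoms$name), atoms$name)
  sprintf("ATOM  %5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          atoms$serial %% 100000L, name, substr(atoms$resname, 1, 4),
          substr(atoms$chain, 1, 1), atoms$resid %% 10000L,
          xyz[, 1], xyz[, 2], xyz[, 3], substr(atoms$element, 1, 2))
}

#' Write a Structure as PDB
#' @param s a `Structure`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_structure <- function(s, path) {
  out <- character(0)
  if (!is.null(s$box)) {
    out <- sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                   s$box[1], s$box[2], s$box[3])
  }
  out <- c(out, format_pdb_atom_lines(s$atoms, coords(s)), "END")
  writeLines(out, path)
  invisible(path)
}

#' Write a Trajectory as multi-model PDB
#'
#' Each frame becomes one `MODEL`/`ENDMDL` block carrying a
#' `REMARK   6 TIME <t> NS` record so that [read_trajectory()] round-trips
#' the time axis.
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  atoms <- traj$topology$atoms
  box <- traj$box
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(box)) {
    writeLines(sprintf("CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
                       box[1], box[2], box[3]), con)
  }
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(sprintf("REMARK   6 TIME %.6f NS", traj$times[i]), con)
    writeLines(format_pdb_atom_lines(atoms, traj$frames[[i]]), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write coordinate frames in the plain-text frame format
#'
#' Format: a header line `natoms nframes`, then per frame one line with the
#' time (ns) followed by `natoms` lines of `x y z` (Angstrom).
#'
#' @param traj a `Trajectory`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_frames <- function(traj, path) {
  na <- n_atoms(traj$topology)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", na, length(traj$frames)), con)
  for (i in seq_along(traj$frames)) {
    writeLines(sprintf("%.6f", traj$times[i]), con)
    fr <- traj$frames[[i]]
    writeLines(sprintf("%.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Selections
# ---------------------------------------------------------------------------

sel_error <- function(expr, pos, msg) {
  stop(sprintf("selection syntax error: %s\n  %s\n  %s^", msg, expr,
               strrep(" ", max(0L, pos - 1L))), call. = FALSE)
}

sel_tokenize <- function(expr) {
  toks <- list()
  i <- 1L
  n <- nchar(expr)
  while (i <= n) {
    ch <- substr(expr, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(text = ch, pos = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(expr, i, n),
                    regexpr("^[A-Za-z0-9_'*:+-]+", substr(expr, i, n)))
    if (length(m) == 0L) sel_error(expr, i, sprintf("unexpected character '%s'", ch))
    toks[[length(toks) + 1L]] <- list(text = m, pos = i)
    i <- i + nchar(m)
  }
  toks
}

#' Parse an atom selection expression
#'
#' Grammar: `name <names>`, `resname <names>`, `resid <ids/ranges>` (ranges
#' `a-b` or `a:b`, inclusive), `chain <ids>`, combined with `and`, `or`,
#' `not` and parentheses. Example: `"name CA and resid 130-146"` picks the
#' C-alpha atoms of a 17-residue helix window. Matching is case-sensitive
#' on atom/residue names. Residue ids follow author numbering.
#'
#' @param expr selection text.
#' @param s a `Structure`.
#' @return an `AtomIndexSet`: list with `indices` (sorted 1-based atom
#'   positions into `s$atoms`) and `label` (the expression; suffixed with
#'   `" [empty]"` when no atom matches).
#' @export
parse_selection <- function(expr, s) {
  if (!inherits(s, "Structure")) stop("s must be a Structure")
  toks <- sel_tokenize(expr)
  if (length(toks) == 0L) sel_error(expr, 1L, "empty expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  advance <- function() { t <- toks[[pos]]; pos <<- pos + 1L; t }
  keywords <- c("name", "resname", "resid", "chain")
  reserved <- c(keywords, "and", "or", "not", "(", ")")

  atoms <- s$atoms
  n <- nrow(atoms)

  parse_primary <- function() {
    tk <- peek()
    if (is.null(tk)) sel_error(expr, nchar(expr) + 1L, "unexpected end of expression")
    if (tk$text == "(") {
      advance()
      v <- parse_or()
      cl <- peek()
      if (is.null(cl) || cl$text != ")") {
        sel_error(expr, if (is.null(cl)) nchar(expr) + 1L else cl$pos,
                  "expected ')'")
      }
      advance()
      return(v)
    }
    kw <- tolower(tk$text)
    if (!(kw %in% keywords)) {
      sel_error(expr, tk$pos, sprintf("expected a keyword (%s), got '%s'",
                                      paste(keywords, collapse = "/"), tk$text))
    }
    advance()
    vals <- character(0)
    repeat {
      nx <- peek()
      if (is.null(nx) || tolower(nx$text) %in% reserved || nx$text %in% c("(", ")")) break
      vals <- c(vals, nx$text)
      advance()
    }
    if (length(vals) == 0L) {
      sel_error(expr, tk$pos + nchar(tk$text),
                sprintf("keyword '%s' needs at least one value", kw))
    }
    switch(kw,
      name = atoms$name %in% vals,
      resname = atoms$resname %in% vals,
      chain = atoms$chain %in% vals,
      resid = {
        mask <- rep(FALSE, n)
        for (v in vals) {
          rng <- regmatches(v, regexec("^([0-9]+)[-:]([0-9]+)$", v))[[1]]
          if (length(rng) == 3L) {
            lo <- as.integer(rng[2]); hi <- as.integer(rng[3])
            mask <- mask | (atoms$resid >= lo & atoms$resid <= hi)
          } else if (grepl("^[0-9]+$", v)) {
            mask <- mask | (atoms$resid == as.integer(v))
          } else {
            sel_error(expr, tk$pos, sprintf("invalid resid value '%s'", v))
          }
        }
        mask
      })
  }
  parse_not <- function() {
    tk <- peek()
    if (!is.null(tk) && tolower(tk$text) == "not") {
      advance()
      return(!parse_not())
    }
    parse_primary()
  }
  parse_and <- function() {
    v <- parse_not()
    repeat {
      tk <- peek()
      if (is.null(tk) || tolower(tk$text) != "and") break
      advance()
      v <- v & parse_not()
    }
    v
  }
  parse_or <- function() {
    v <- parse_and()
    repeat {
      tk <- peek()
      if (is.null(tk) || tolower(tk$text) != "or") break
      advance()
      v <- v | parse_and()
    }
    v
  }

  mask <- parse_or()
  if (pos <= length(toks)) {
    sel_error(expr, toks[[pos]]$pos,
              sprintf("unexpected token '%s'", toks[[pos]]$text))
  }
  idx <- which(mask)
  label <- if (length(idx) == 0L) paste0(expr, " [empty]") else expr
  structure(list(indices = idx, label = label), class = "AtomIndexSet")
}

#' Build an AtomIndexSet from raw indices
#' @param indices 1-based positions into the structure's atom table.
#' @param label text label.
#' @param s optional `Structure` for range validation.
#' @return an `AtomIndexSet`.
#' @export
atom_index_set <- function(indices, label = "custom", s = NULL) {
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) > 0L && indices[1] < 1L) stop("indices must be >= 1")
  if (!is.null(s) && length(indices) > 0L && max(indices) > n_atoms(s)) {
    stop("indices out of range for structure")
  }
  structure(list(indices = indices, label = label), class = "AtomIndexSet")
}

resolve_selection <- function(sel, s) {
  if (inherits(sel, "AtomIndexSet")) return(sel)
  if (is.character(sel) && length(sel) == 1L) return(parse_selection(sel, s))
  if (is.numeric(sel)) return(atom_index_set(sel, s = s))
  stop("selection must be an AtomIndexSet, a selection string, or indices")
}

# ---------------------------------------------------------------------------
# Tabular output
# ---------------------------------------------------------------------------

#' Write records as a TSV table
#'
#' Writes UTF-8 tab-separated values with a header line; numeric columns are
#' formatted at 6 significant digits.
#'
#' @param rows data.frame of homogeneous records (zero rows allowed: a
#'   header-only file is written).
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) rows <- as.data.frame(rows)
  fmt <- rows
  for (j in seq_along(fmt)) {
    if (is.double(fmt[[j]])) {
      fmt[[j]] <- formatC(fmt[[j]], digits = 6, format = "g")
    }
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(fmt, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV table written by [write_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}
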