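#' Append one XYZ trajectory frame
#'
#' Writes the conformation as one frame of an XYZ-format trajectory so
#' that standard molecular viewers can render snapshots: first line the
#' bead count, second line the comment `mcs=<value>`, then one line per
#' bead, vesicle beads first (`V x y 0.0`) followed by polymer beads
#' (`P x y 0.0`), coordinates at 12 significant digits, `z` always 0.
#'
#' @param conf a [conformation()].
#' @param mcs the MCS index of the frame.
#' @param sink a connection or file path (appended to).
#' @return `NULL`, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory_frame <- function(conf, mcs, sink) {
  own <- FALSE
  if (is.character(sink)) {
    sink <- file(sink, open = "a"); own <- TRUE
    on.exit(close(sink))
  }
  nv <- nrow(conf$vesicle_xy); np <- nrow(conf$polymer_xy)
  lines <- c(
    as.character(nv + np),
    sprintf("mcs=%s", format(mcs, scientific = FALSE)),
    sprintf("V %.12g %.12g 0.0", conf$vesicle_xy[, 1], conf$vesicle_xy[, 2]),
    sprintf("P %.12g %.12g 0.0", conf$polymer_xy[, 1], conf$polymer_xy[, 2]))
  writeLines(lines, sink)
  invisible(NULL)
}

#' Read an XYZ trajectory written by [write_trajectory_frame()]
#'
#' @param path trajectory file.
#' @return A list of frames, each a list with `mcs` and `conformation`.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    mcs <- as.numeric(sub("^mcs=", "", lines[i + 1L]))
    body <- lines[(i + 2L):(i + 1L + n)]
    tags <- substr(body, 1, 1)
    parts <- strsplit(body, "\\s+")
    xy <- t(vapply(parts, function(p) as.numeric(p[2:3]), c(0, 0)))
    frames[[length(frames) + 1L]] <- list(
      mcs = mcs,
      conformation = conformation(xy[tags == "V", , drop = FALSE],
                                  xy[tags == "P", , drop = FALSE]))
    i <- i + 2L + n
  }
  frames
}

#' Write a checkpoint
#'
#' Flat-text snapshot of the full simulation state: model parameters, the
#' random stream state, and one bead per line (`chain-tag index x y` at
#' full double precision). Round-trips bit-exactly through
#' [read_checkpoint()].
#'
#' @param conf a [conformation()].
#' @param params a [model_params()] object.
#' @param rng an [mc_rng()] stream (its state token is stored).
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_checkpoint <- function(conf, params, rng, path) {
  hdr <- c("# vesimorph checkpoint v1",
           vapply(.param_keys, function(k)
             sprintf("param %s %.17g", k, as.numeric(params[[k]])), ""),
           paste("rng", paste(format(rng_state(rng), scientific = FALSE,
                                     trim = TRUE), collapse = " ")))
  body <- c(
    sprintf("V %d %.17g %.17g", seq_len(nrow(conf$vesicle_xy)),
            conf$vesicle_xy[, 1], conf$vesicle_xy[, 2]),
    sprintf("P %d %.17g %.17g", seq_len(nrow(conf$polymer_xy)),
            conf$polymer_xy[, 1], conf$polymer_xy[, 2]))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a checkpoint written by [write_checkpoint()]
#'
#' @param path checkpoint file.
#' @return A list: `conformation`, `params`, `rng` (restored stream).
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  parts <- strsplit(lines, "\\s+")
  tag <- vapply(parts, `[`, "", 1L)

  pk <- parts[tag == "param"]
  args <- lapply(pk, function(p) as.numeric(p[3]))
  names(args) <- vapply(pk, `[`, "", 2L)
  args$r0 <- NULL
  params <- do.call(model_params, args)

  rng_words <- as.numeric(parts[tag == "rng"][[1]][-1])
  rng <- mc_rng(state = rng_words)

  get_xy <- function(t) {
    rows <- parts[tag == t]
    ord <- order(vapply(rows, function(p) as.integer(p[2]), 0L))
    t(vapply(rows[ord], function(p) as.numeric(p[3:4]), c(0, 0)))
  }
  list(conformation = conformation(get_xy("V"), get_xy("P")),
       params = params, rng = rng)
}

#' Write a pooled measurement table
#'
#' Tab-delimited with header `run, seed, mcs, u_vl, r_ee, asphericity,
#' shape_label`.
#'
#' @param result a `replica_result` from [run_replicas()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(result, path) {
  rec <- result$records[, c("run", "seed", "mcs", "u_vl", "r_ee",
                            "asphericity", "shape_label")]
  utils::write.table(rec, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a correlation curve table
#'
#' Tab-delimited with columns `s`, `C_mean`, `C_stderr`.
#'
#' @param result a `replica_result` from [run_replicas()].
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_correlation <- function(result, path) {
  utils::write.table(result$tt_corr, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
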