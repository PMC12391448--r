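# Circuit serialization: JSON round-trip and OpenQASM 2.0 text export/import.

#' Serialize a circuit to JSON
#'
#' @param spec A [circuit_spec()].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return A JSON string (invisibly, when writing to a file).
#' @seealso [circuit_from_json()]
#' @export
circuit_to_json <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  obj <- list(
    n_qubits = spec$n_qubits,
    ops = lapply(spec$ops, function(op) {
      list(kind = op$kind, targets = op$targets, angles = op$angles)
    })
  )
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize a circuit from JSON
#'
#' @param json A JSON string or a path to a JSON file produced by
#'   [circuit_to_json()].
#' @return A [circuit_spec()].
#' @export
circuit_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  ops <- lapply(obj$ops, function(o) {
    gate_op(o$kind,
            vapply(o$targets, as.integer, integer(1)),
            if (is.null(o$angles)) numeric(0) else
              vapply(o$angles, as.numeric, numeric(1)))
  })
  circuit_spec(as.integer(obj$n_qubits), ops)
}

#' Export a circuit as OpenQASM 2.0 text
#'
#' Emits one quantum register `q` and the instructions `h`, `ry`, `rz`,
#' `u3` and `cz`. Angles are printed with full double precision so a
#' round trip through [circuit_from_qasm()] reproduces the gate list and
#' angles beyond 12 decimal digits.
#'
#' @param spec A [circuit_spec()].
#' @param path Optional file path; when `NULL` the program text is returned.
#' @return A character scalar with the QASM program (invisibly when writing).
#' @export
circuit_to_qasm <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "circuit_spec"))
  fmt <- function(x) sprintf("%.17g", x)
  lines <- c(
    "OPENQASM 2.0;",
    "include \"qelib1.inc\";",
    sprintf("qreg q[%d];", spec$n_qubits),
    vapply(spec$ops, function(op) {
      switch(op$kind,
        H  = sprintf("h q[%d];", op$targets[1]),
        RY = sprintf("ry(%s) q[%d];", fmt(op$angles[1]), op$targets[1]),
        RZ = sprintf("rz(%s) q[%d];", fmt(op$angles[1]), op$targets[1]),
        U3 = sprintf("u3(%s,%s,%s) q[%d];", fmt(op$angles[1]),
                     fmt(op$angles[2]), fmt(op$angles[3]), op$targets[1]),
        CZ = sprintf("cz q[%d],q[%d];", op$targets[1], op$targets[2])
      )
    }, character(1))
  )
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Parse OpenQASM 2.0 text into a circuit
#'
#' Accepts the subset emitted by [circuit_to_qasm()]: a single `qreg` and
#' `h`, `ry`, `rz`, `u3`, `cz` instructions.
#'
#' @param text QASM program text (or a path to a `.qasm` file).
#' @return A [circuit_spec()].
#' @export
circuit_from_qasm <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "\n")
  }
  lines <- strsplit(paste(text, collapse = "\n"), "\n")[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  n_qubits <- NA_integer_
  ops <- list()
  for (ln in lines) {
    if (grepl("^(OPENQASM|include)", ln)) next
    m <- regmatches(ln, regexec("^qreg\\s+\\w+\\[(\\d+)\\];", ln))[[1]]
    if (length(m)) { n_qubits <- as.integer(m[2]); next }
    m <- regmatches(ln, regexec("^h\\s+\\w+\\[(\\d+)\\];", ln))[[1]]
    if (length(m)) { ops[[length(ops) + 1L]] <- gate_op("H", as.integer(m[2])); next }
    m <- regmatches(ln, regexec("^(ry|rz)\\(([^)]+)\\)\\s+\\w+\\[(\\d+)\\];", ln))[[1]]
    if (length(m)) {
      ops[[length(ops) + 1L]] <- gate_op(toupper(m[2]), as.integer(m[4]),
                                         as.numeric(m[3]))
      next
    }
    m <- regmatches(ln, regexec("^u3\\(([^)]+)\\)\\s+\\w+\\[(\\d+)\\];", ln))[[1]]
    if (length(m)) {
      ang <- as.numeric(strsplit(m[2], ",")[[1]])
      ops[[length(ops) + 1L]] <- gate_op("U3", as.integer(m[3]), ang)
      next
    }
    m <- regmatches(ln, regexec("^cz\\s+\\w+\\[(\\d+)\\],\\s*\\w+\\[(\\d+)\\];", ln))[[1]]
    if (length(m)) {
      ops[[length(ops) + 1L]] <- gate_op("CZ", c(as.integer(m[2]), as.integer(m[3])))
      next
    }
    stop("unrecognized QASM instruction: ", ln, call. = FALSE)
  }
  if (is.na(n_qubits)) stop("QASM program has no qreg declaration", call. = FALSE)
  circuit_spec(n_qubits, ops)
}
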