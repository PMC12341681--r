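# Minimal MathML <-> R-expression translation for SBML kinetic laws.
# Supports the arithmetic subset rate laws need: +, -, *, /, ^, symbols and
# numeric literals (including e-notation). Anything else is rejected with
# the offending element named.

.mathml_ops <- c(plus = "+", minus = "-", times = "*", divide = "/",
                 power = "^")

# R expression string -> MathML content string (no <math> wrapper)
expr_to_mathml <- function(text) {
  rec <- function(e) {
    if (is.numeric(e)) {
      if (e < 0) return(paste0("<apply><minus/>", rec(-e), "</apply>"))
      return(paste0("<cn>", format(e, scientific = FALSE, digits = 17),
                    "</cn>"))
    }
    if (is.name(e)) return(paste0("<ci> ", as.character(e), " </ci>"))
    if (is.call(e)) {
      op <- as.character(e[[1]])
      if (op == "(") return(rec(e[[2]]))
      tag <- names(.mathml_ops)[match(op, .mathml_ops)]
      if (is.na(tag)) stop("unsupported operator in rate law: ", op)
      args <- vapply(as.list(e)[-1], rec, "")
      return(paste0("<apply><", tag, "/>", paste(args, collapse = ""),
                    "</apply>"))
    }
    stop("unsupported rate-law element: ", deparse(e))
  }
  rec(str2lang(text))
}

# MathML node (an <apply>/<ci>/<cn>, or the <math> wrapper) -> R expression
# string. Namespaces are assumed stripped.
mathml_to_expr <- function(node) {
  name <- xml2::xml_name(node)
  kids <- function(n) xml2::xml_find_all(n, "./*")
  if (name == "math") {
    ch <- kids(node)
    if (length(ch) != 1) stop("malformed <math>: expected one child")
    return(mathml_to_expr(ch[[1]]))
  }
  if (name == "ci") return(trimws(xml2::xml_text(node)))
  if (name == "cn") {
    type <- xml2::xml_attr(node, "type")
    if (!is.na(type) && type == "e-notation") {
      parts <- trimws(strsplit(xml2::xml_text(node), "\\s+")[[1]])
      parts <- parts[nzchar(parts)]
      return(format(as.numeric(parts[1]) * 10^as.numeric(parts[2]),
                    scientific = FALSE, digits = 17))
    }
    return(trimws(xml2::xml_text(node)))
  }
  if (name == "apply") {
    ch <- kids(node)
    op_tag <- xml2::xml_name(ch[[1]])
    op <- .mathml_ops[[op_tag]]
    if (is.null(op)) stop("unsupported MathML operator: <", op_tag, "/>")
    args <- vapply(ch[-1], mathml_to_expr, "")
    if (length(args) == 1 && op == "-") return(paste0("-(", args, ")"))
    if (length(args) < 2) stop("malformed <apply> with operator ", op_tag)
    return(paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")"))
  }
  stop("unsupported MathML element: <", name, ">")
}
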