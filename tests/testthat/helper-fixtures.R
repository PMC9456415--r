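# Shared in-code fixtures. The three sterol retrieve sequences mirror the
# package's worked example (see example_retrieves()) but are constructed
# here independently so unit tests do not depend on the extdata file.

sterol_seq <- function(which = c("hydroxystigmast", "sitosterol",
                                 "campesterol")) {
  which <- match.arg(which)
  switch(which,
    hydroxystigmast = retrieve_sequence(
      "3-Hydroxystigmast-5-en-7-one", "Hepatotoxicity",
      score = c(0.992, 0.986, 0.976, 0.917, 0.540, 0.520, 0.498, 0.302),
      verdict = c(0, 0, NA, 0, 0, 0, -1, 1),
      cid = c("6010", "10631", "5997", "6917715", "54454", "53232",
              "5280453", "445354")
    ),
    sitosterol = retrieve_sequence(
      "beta-sitosterol", "Hepatotoxicity",
      score = c(0.999, 0.804, 0.588, 0.588),
      verdict = c(NA, -1, 1, 1),
      cid = c("5997", "5280453", "445354", "445354")
    ),
    campesterol = retrieve_sequence(
      "campesterol", "Hepatotoxicity",
      score = c(0.999, 0.836, 0.594),
      verdict = c(NA, -1, 1),
      cid = c("5997", "5280453", "445354")
    )
  )
}

toy_compound_table <- function() {
  data.frame(
    name = sprintf("cmp%d", 1:5),
    smiles = c("CCO", "c1ccccc1", "CC(=O)O", "c1ccccc1O", "CCN"),
    ob = c(0.1, 0.3, 0.5, 0.35, 0.2),
    dl = c(0.2, 0.18, 0.1, 0.5, 0.3),
    herb = "Herba alpha",
    stringsAsFactors = FALSE
  )
}
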