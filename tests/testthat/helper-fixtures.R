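# Shared fixtures: everything is generated in code at test time.

defaultParams <- tsWtaParams()

# the canonical 8-stimulus training set for a 9 x 9 field (4 disparities
# plus complements), fixed seed so tests share one set
patternSet9 <- makePatternSet(9, 9, 4, seed = 7)
basePatterns9 <- patternSet9[1:4]

# a receptive field saturated on a pattern's template: the ON synapse at the
# bottom rail, the OFF synapse at the top rail
saturatedField <- function(pattern, params = defaultParams) {
  b <- pattern@bits
  new("ReceptiveField",
      vfg1 = matrix(ifelse(b == 1, params@vfgMin, params@vfgMax), nrow(b)),
      vfg2 = matrix(ifelse(b == 1, params@vfgMax, params@vfgMin), nrow(b)),
      wL = pattern@wL, wR = pattern@wR, initRange = c(4.8, 5.5))
}

# a field with every floating gate equal (fully undeveloped, symmetric)
flatField <- function(h, w, level = 5.0) {
  sw <- splitWidth(w)
  new("ReceptiveField", vfg1 = matrix(level, h, w), vfg2 = matrix(level, h, w),
      wL = unname(sw["wL"]), wR = unname(sw["wR"]), initRange = c(4.8, 5.5))
}

twoCellTopology <- matrix(c(0, 1, 1, 0), 2, 2)
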