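Place transcribed supplementary HWI matrices here (not distributed with the
package). Each file is a square CSV in the shape written by
write_association_matrix(): a header row and an index column of individual
codes, values to 4 decimal places.

Expected files:
  hwi_pooled.csv   pooled 2009-2014 matrix (22 males)
  hwi_T1.csv       2009-2010
  hwi_T2.csv       2011-2012
  hwi_T3.csv       2013-2014

An alternative directory can be set with
  options(alliancenet.supplementary_dir = "/path/to/dir")
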