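# Four-iteration schedule for eleven input batches: iteration 1 clusters
# each batch separately; iteration 2 combines outputs 1-3, 4-7 and 8-11;
# iteration 3 combines the first two of those while 8-9-10-11 carries
# forward; iteration 4 clusters everything in one final batch.
iterations:
  - - ["1", "2", "3"]
    - ["4", "5", "6", "7"]
    - ["8", "9", "10", "11"]
  - - ["1-2-3", "4-5-6-7"]
  - - ["1-2-3-4-5-6-7", "8-9-10-11"]
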