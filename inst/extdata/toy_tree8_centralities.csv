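# relative betweenness of the 8-node toy tree (n=8, denominator (n-1)(n-2)/2 = 21)
# computed by hand from component sizes after removing each node:
# pairs through a tree node = sum over component pairs of size products
compound,pairs_through,relative_betweenness
n1,0,0
n2,6,0.2857142857142857
n3,16,0.7619047619047619
n4,6,0.2857142857142857
n5,0,0
n6,11,0.5238095238095238
n7,0,0
n8,0,0
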