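!name nei5
!species E S ES1 ES2 ES3 EP P
E + S <-> ES1 : k1/k_1
ES1 <-> ES2 : k2/k_2
ES2 <-> ES3 : k3/k_3
ES3 -> EP : kcat
EP <-> E + P : koff/kon
!derived kon = koff/KP
!default koff = 10
!conserve E ES1 ES2 ES3 EP
!conserve S ES1 ES2 ES3 EP P
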