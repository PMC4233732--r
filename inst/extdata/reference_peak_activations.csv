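muscle,mode,side,activation
superficial_masseter,shearing,balancing,11.3
superficial_masseter,shearing,working,31.6
superficial_masseter,crushing,balancing,29.3
superficial_masseter,crushing,working,6.9
superficial_masseter,incisor,both,38.7
posterior_deep_masseter,shearing,balancing,80.2
posterior_deep_masseter,shearing,working,45.3
posterior_deep_masseter,crushing,balancing,31.4
posterior_deep_masseter,crushing,working,100.0
posterior_deep_masseter,incisor,both,100.0
anterior_zygomaticomandibularis,shearing,balancing,33.3
anterior_zygomaticomandibularis,shearing,working,17.3
anterior_zygomaticomandibularis,crushing,balancing,13.1
anterior_zygomaticomandibularis,crushing,working,43.9
anterior_zygomaticomandibularis,incisor,both,70.0
posterior_zygomaticomandibularis,shearing,balancing,65.7
posterior_zygomaticomandibularis,shearing,working,41.1
posterior_zygomaticomandibularis,crushing,balancing,25.7
posterior_zygomaticomandibularis,crushing,working,99.1
posterior_zygomaticomandibularis,incisor,both,100.0
superficial_temporalis,shearing,balancing,100.0
superficial_temporalis,shearing,working,83.9
superficial_temporalis,crushing,balancing,49.8
superficial_temporalis,crushing,working,100.0
superficial_temporalis,incisor,both,100.0
deep_temporalis,shearing,balancing,61.6
deep_temporalis,shearing,working,73.8
deep_temporalis,crushing,balancing,82.3
deep_temporalis,crushing,working,65.1
deep_temporalis,incisor,both,100.0
medial_pterygoid,shearing,balancing,17.7
medial_pterygoid,shearing,working,28.6
medial_pterygoid,crushing,balancing,46.2
medial_pterygoid,crushing,working,11.2
medial_pterygoid,incisor,both,62.3
lateral_pterygoid,shearing,balancing,72.6
lateral_pterygoid,shearing,working,5.5
lateral_pterygoid,crushing,balancing,50.6
lateral_pterygoid,crushing,working,2.2
lateral_pterygoid,incisor,both,11.4
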