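class,village,type,n
post-boom,A,Androstachys forest,0
post-boom,A,Mopane woodland,3
post-boom,A,Combretum woodland,4
post-boom,A,Boscia woodland,13
post-boom,A,shrub Mopane,3
post-boom,B,Androstachys forest,0
post-boom,B,Mopane woodland,19
post-boom,B,Combretum woodland,4
post-boom,B,Boscia woodland,0
post-boom,B,shrub Mopane,0
post-boom,C,Androstachys forest,0
post-boom,C,Mopane woodland,11
post-boom,C,Combretum woodland,9
post-boom,C,Boscia woodland,0
post-boom,C,shrub Mopane,0
boom,D,Androstachys forest,6
boom,D,Mopane woodland,1
boom,D,Combretum woodland,12
boom,D,Boscia woodland,0
boom,D,shrub Mopane,0
boom,E,Androstachys forest,5
boom,E,Mopane woodland,1
boom,E,Combretum woodland,17
boom,E,Boscia woodland,0
boom,E,shrub Mopane,0
pre-boom,F,Androstachys forest,7
pre-boom,F,Mopane woodland,14
pre-boom,F,Combretum woodland,2
pre-boom,F,Boscia woodland,0
pre-boom,F,shrub Mopane,0
pre-boom,G,Androstachys forest,6
pre-boom,G,Mopane woodland,2
pre-boom,G,Combretum woodland,15
pre-boom,G,Boscia woodland,0
pre-boom,G,shrub Mopane,0
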